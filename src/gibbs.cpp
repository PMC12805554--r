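// Gibbs sampler for the latent-factor spatial causal model and its two
// baseline variants. All full conditionals are conjugate (probit data
// augmentation for the treatment equations); the only Metropolis step is
// the half-normal-prior random-effect scale tau.
//
// Parameterization (identification normalization): treatment-index error
// variance fixed at 1, latent confounder U has prior N(0, I_q), and the
// first row of each loading column of alpha_wu is kept positive by joint
// sign flips of (alpha_wu[,c], alpha_yu[c], alpha_au[c,], U[,c]).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec rnvec(int n) {
  vec v(n);
  for (int i = 0; i < n; i++) v(i) = R::norm_rand();
  return v;
}

static mat rnmat(int n, int m) {
  mat v(n, m);
  for (int j = 0; j < m; j++)
    for (int i = 0; i < n; i++) v(i, j) = R::norm_rand();
  return v;
}

// One-sided truncated standard normal: Z | Z > a. Inversion is unstable far
// in the tail; switch to Robert's translated-exponential rejection there.
static double rtnorm_std_lower(double a) {
  if (a < 0.45) {
    double z;
    do { z = R::norm_rand(); } while (z <= a);
    return z;
  }
  double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double z = a + R::exp_rand() / alpha;
    double d = z - alpha;
    if (R::unif_rand() <= std::exp(-0.5 * d * d)) return z;
  }
}

// N(mu, sd^2) truncated to (0, inf) if positive, else (-inf, 0].
static double rtnorm(double mu, double sd, bool positive) {
  if (positive) return mu + sd * rtnorm_std_lower(-mu / sd);
  return mu - sd * rtnorm_std_lower(mu / sd);
}

// [[Rcpp::export]]
Rcpp::NumericVector rtnorm_cpp(int n, double mu, double sd, bool positive) {
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = rtnorm(mu, sd, positive);
  return out;
}

// Inverse-gamma draw with shape a, rate b (mean b / (a - 1)).
static double rinvgamma(double a, double b) {
  return 1.0 / R::rgamma(a, 1.0 / b);
}

// Sample beta[free] from its conjugate normal full conditional in the
// regression yv = X beta + N(0, sig2), prior N(0, 1/prior_prec) elementwise,
// holding beta[frozen] fixed (absorbed into the response as an offset).
static void update_block(const mat& X, const vec& yv, double sig2,
                         double prior_prec, const uvec& free_idx, vec& beta) {
  if (free_idx.n_elem == 0) return;
  vec r = yv - X * beta + X.cols(free_idx) * beta(free_idx);
  mat Xf = X.cols(free_idx);
  mat P = Xf.t() * Xf / sig2;
  P.diag() += prior_prec;
  vec b = Xf.t() * r / sig2;
  mat R = chol(P);                      // upper: P = R'R
  vec mu = solve(trimatu(R), solve(trimatl(R.t()), b));
  beta(free_idx) = mu + solve(trimatu(R), rnvec(free_idx.n_elem));
}

// [[Rcpp::export]]
Rcpp::List gibbs_fit_cpp(const arma::vec& y, const arma::mat& Tmat,
                         const arma::mat& W, const arma::uvec& city,
                         const Rcpp::List& B_list,
                         int variant,           // 0 latent, 1 proxy-reg, 2 none
                         int q, bool random_effect,
                         int n_burn, int n_keep, int thin,
                         double coef_sd, double ig_shape, double ig_rate,
                         double tau_sd,
                         const Rcpp::List& init, const Rcpp::List& upd) {
  const int n = y.n_elem;
  const int K = Tmat.n_cols;
  const int M = B_list.size();
  const int p = W.n_cols;
  const bool latent = (variant == 0);
  const bool proxy_cov = (variant == 1);
  const double prior_prec = 1.0 / (coef_sd * coef_sd);

  // per-city row ranges (rows are sorted by city) and basis matrices
  std::vector<mat> B(M), BtB(M);
  uvec row0(M), row1(M);
  int Ltot = 0;
  {
    int pos = 0;
    for (int i = 0; i < M; i++) {
      B[i] = Rcpp::as<mat>(B_list[i]);
      BtB[i] = B[i].t() * B[i];
      row0(i) = pos;
      pos += B[i].n_rows;
      row1(i) = pos - 1;
      Ltot += B[i].n_cols;
    }
    if (pos != n) Rcpp::stop("basis rows do not match data rows");
  }
  const bool has_z = Ltot > 0;

  // outcome design layout: [1 | T (unless RE) | U | W | Z]
  const int nT = random_effect ? 0 : K;
  const int nU = latent ? q : 0;
  const int nW = proxy_cov ? p : 0;
  const int iT = 1, iU = iT + nT, iW = iU + nU, iZ = iW + nW;
  const int Pout = 1 + nT + nU + nW + (has_z ? 1 : 0);
  const int Pa = 1 + (latent ? q : 0) + (has_z ? 1 : 0);

  // state
  vec beta_out = Rcpp::as<vec>(init["beta_out"]);       // length Pout
  mat beta_a = Rcpp::as<mat>(init["beta_a"]);           // Pa x K
  vec alpha_w = p > 0 ? Rcpp::as<vec>(init["alpha_w"]) : vec();
  mat alpha_wu = latent ? Rcpp::as<mat>(init["alpha_wu"]) : mat(); // p x q
  double sigma_y2 = Rcpp::as<double>(init["sigma_y2"]);
  vec sigma_w2 = p > 0 ? Rcpp::as<vec>(init["sigma_w2"]) : vec();
  double sigma_z2 = Rcpp::as<double>(init["sigma_z2"]);
  mat U = latent ? Rcpp::as<mat>(init["U"]) : mat(n, 0);
  std::vector<vec> lambda(M);
  for (int i = 0; i < M; i++) lambda[i] = zeros<vec>(B[i].n_cols);
  mat theta_city = Rcpp::as<mat>(init["theta_city"]);   // M x K (RE mode)
  vec theta_bar = Rcpp::as<vec>(init["theta_bar"]);     // K (RE mode)
  vec tau2 = Rcpp::as<vec>(init["tau2"]);               // K (RE mode)
  mat Astar(n, K, fill::zeros);

  // update flags (frozen blocks keep their init values)
  uvec free_out = Rcpp::as<uvec>(upd["free_out"]);      // 0-based cols of X_out
  const bool upd_treat = Rcpp::as<bool>(upd["treat"]);
  const bool upd_w_int = Rcpp::as<bool>(upd["w_intercept"]);
  mat upd_w_load = latent ? Rcpp::as<mat>(upd["w_load"]) : mat();   // p x q 0/1
  const bool upd_sig_y = Rcpp::as<bool>(upd["sigma_y"]);
  const bool upd_sig_w = Rcpp::as<bool>(upd["sigma_w"]);
  const bool upd_sig_z = Rcpp::as<bool>(upd["sigma_z"]);
  const bool upd_lambda = Rcpp::as<bool>(upd["lambda"]);
  const bool upd_u = Rcpp::as<bool>(upd["u"]);
  const bool sign_identify = Rcpp::as<bool>(upd["sign_identify"]);

  vec Z = zeros<vec>(n);
  auto refresh_Z = [&]() {
    for (int i = 0; i < M; i++)
      if (B[i].n_cols > 0)
        Z.subvec(row0(i), row1(i)) = B[i] * lambda[i];
  };
  refresh_Z();

  mat X_out(n, Pout);
  X_out.col(0).ones();
  if (nT > 0) X_out.cols(iT, iT + K - 1) = Tmat;
  auto refresh_Xout = [&]() {
    if (nU > 0) X_out.cols(iU, iU + q - 1) = U;
    if (nW > 0) X_out.cols(iW, iW + p - 1) = W;
    if (has_z) X_out.col(iZ) = Z;
  };
  refresh_Xout();

  mat X_a(n, Pa);
  X_a.col(0).ones();
  auto refresh_Xa = [&]() {
    if (latent && q > 0) X_a.cols(1, q) = U;
    if (has_z) X_a.col(Pa - 1) = Z;
  };
  refresh_Xa();

  auto re_offset = [&](vec& off) {
    off.zeros();
    if (!random_effect) return;
    for (int i = 0; i < M; i++)
      for (int k = 0; k < K; k++)
        off.subvec(row0(i), row1(i)) +=
          theta_city(i, k) * Tmat(span(row0(i), row1(i)), span(k, k));
  };
  vec off(n, fill::zeros);
  re_offset(off);

  const int n_save = n_keep / thin;
  mat save_theta(n_save, K);
  mat save_theta_city(random_effect ? n_save : 0, M * K);
  mat save_tau2(random_effect ? n_save : 0, K);
  mat save_beta_out(n_save, Pout);
  mat save_beta_a(n_save, Pa * K);
  mat save_alpha_w(n_save, p);
  mat save_alpha_wu(n_save, latent ? p * q : 0);
  mat save_sigma(n_save, 2 + p);        // sigma_y2, sigma_z2, sigma_w2...
  mat save_loglik(n_save, n);
  mat U_mean(n, nU, fill::zeros);
  int saved = 0;

  const int n_iter = n_burn + n_keep;
  for (int it = 0; it < n_iter; it++) {
    // (i) probit augmentation
    for (int k = 0; k < K; k++) {
      vec mu_a = X_a * beta_a.col(k);
      for (int j = 0; j < n; j++)
        Astar(j, k) = rtnorm(mu_a(j), 1.0, Tmat(j, k) > 0.5);
    }

    // (ii) latent confounder U
    if (latent && upd_u && q > 0) {
      vec a_yu = beta_out.subvec(iU, iU + q - 1);
      mat P_u = eye(q, q) + a_yu * a_yu.t() / sigma_y2;
      for (int k = 0; k < K; k++) {
        vec a_au = beta_a.col(k).subvec(1, q);
        P_u += a_au * a_au.t();
      }
      mat WiL = alpha_wu.each_col() / sigma_w2;   // p x q: Sigma_w^-1 alpha_wu
      P_u += alpha_wu.t() * WiL;

      vec mu_y = X_out * beta_out + off;
      mat RHS = (y - mu_y + U * a_yu) * a_yu.t() / sigma_y2;
      for (int k = 0; k < K; k++) {
        vec a_au = beta_a.col(k).subvec(1, q);
        vec mu_ak = X_a * beta_a.col(k);
        RHS += (Astar.col(k) - mu_ak + U * a_au) * a_au.t();
      }
      mat Rw = W;
      Rw.each_row() -= alpha_w.t();
      RHS += Rw * WiL;

      mat Ru = chol(P_u);               // upper
      U = solve(P_u, RHS.t()).t() + rnmat(n, q) * inv(trimatu(Ru)).t();
      refresh_Xout();
      refresh_Xa();
    }

    // (iii) outcome coefficient block
    update_block(X_out, y - off, sigma_y2, prior_prec, free_out, beta_out);

    // (iv) treatment coefficient blocks (index error variance fixed at 1)
    if (upd_treat) {
      uvec all_a = regspace<uvec>(0, Pa - 1);
      for (int k = 0; k < K; k++) {
        vec bk = beta_a.col(k);
        update_block(X_a, Astar.col(k), 1.0, prior_prec, all_a, bk);
        beta_a.col(k) = bk;
      }
    }

    // (v) proxy measurement equations + sign identification
    if (latent && p > 0) {
      mat Xw(n, 1 + q);
      Xw.col(0).ones();
      Xw.cols(1, q) = U;
      for (int k = 0; k < p; k++) {
        vec bw(1 + q);
        bw(0) = alpha_w(k);
        bw.subvec(1, q) = alpha_wu.row(k).t();
        std::vector<arma::uword> fr;
        if (upd_w_int) fr.push_back(0);
        for (int c = 0; c < q; c++)
          if (upd_w_load(k, c) > 0.5) fr.push_back(1 + c);
        uvec free_w(fr);
        update_block(Xw, W.col(k), sigma_w2(k), prior_prec, free_w, bw);
        alpha_w(k) = bw(0);
        alpha_wu.row(k) = bw.subvec(1, q).t();
      }
      if (sign_identify) {
        for (int c = 0; c < q; c++) {
          if (alpha_wu(0, c) < 0) {
            alpha_wu.col(c) *= -1.0;
            beta_out(iU + c) *= -1.0;
            for (int k = 0; k < K; k++) beta_a(1 + c, k) *= -1.0;
            U.col(c) *= -1.0;
          }
        }
        refresh_Xout();
        refresh_Xa();
      }
    }

    // (vi) spline coefficients lambda (city by city)
    if (has_z && upd_lambda) {
      double a_yz = beta_out(iZ);
      vec mu_y = X_out * beta_out + off;
      vec ry = y - mu_y + a_yz * Z;     // outcome residual excluding Z term
      double w_prec = a_yz * a_yz / sigma_y2;
      std::vector<vec> ra(K);
      for (int k = 0; k < K; k++) {
        double a_az = beta_a(Pa - 1, k);
        ra[k] = Astar.col(k) - X_a * beta_a.col(k) + a_az * Z;
        w_prec += a_az * a_az;
      }
      for (int i = 0; i < M; i++) {
        int Li = B[i].n_cols;
        if (Li == 0) continue;
        mat P = w_prec * BtB[i];
        P.diag() += 1.0 / sigma_z2;
        vec b = (a_yz / sigma_y2) *
          (B[i].t() * ry.subvec(row0(i), row1(i)));
        for (int k = 0; k < K; k++) {
          double a_az = beta_a(Pa - 1, k);
          b += a_az * (B[i].t() * ra[k].subvec(row0(i), row1(i)));
        }
        mat R = chol(P);
        vec mu = solve(trimatu(R), solve(trimatl(R.t()), b));
        lambda[i] = mu + solve(trimatu(R), rnvec(Li));
      }
      refresh_Z();
      refresh_Xout();
      refresh_Xa();
    }

    // (vii) variances
    {
      vec res_y = y - X_out * beta_out - off;
      if (upd_sig_y)
        sigma_y2 = rinvgamma(ig_shape + 0.5 * n,
                             ig_rate + 0.5 * dot(res_y, res_y));
      if (latent && upd_sig_w) {
        for (int k = 0; k < p; k++) {
          vec rw = W.col(k) - alpha_w(k) - U * alpha_wu.row(k).t();
          sigma_w2(k) = rinvgamma(ig_shape + 0.5 * n,
                                  ig_rate + 0.5 * dot(rw, rw));
        }
      }
      if (has_z && upd_sig_z) {
        double ss = 0.0;
        for (int i = 0; i < M; i++) ss += dot(lambda[i], lambda[i]);
        sigma_z2 = rinvgamma(ig_shape + 0.5 * Ltot, ig_rate + 0.5 * ss);
      }
    }

    // (viii) random-effect treatment coefficients and hyperparameters
    if (random_effect) {
      vec mu_fix = X_out * beta_out;
      for (int k = 0; k < K; k++) {
        for (int i = 0; i < M; i++) {
          span rows(row0(i), row1(i));
          vec x = Tmat(rows, span(k, k));
          double sx2 = dot(x, x);
          // residual for city i excluding this theta_{ik} term
          vec r = y(rows) - mu_fix(rows) - off(rows) +
            theta_city(i, k) * x;
          double prec = sx2 / sigma_y2 + 1.0 / tau2(k);
          double mean = (dot(x, r) / sigma_y2 + theta_bar(k) / tau2(k)) / prec;
          double old = theta_city(i, k);
          theta_city(i, k) = mean + R::norm_rand() / std::sqrt(prec);
          off(rows) += (theta_city(i, k) - old) * x;
        }
        // population mean
        double prec = M / tau2(k) + prior_prec;
        double mean = accu(theta_city.col(k)) / tau2(k) / prec;
        theta_bar(k) = mean + R::norm_rand() / std::sqrt(prec);
        // tau: random-walk Metropolis on log tau, half-normal prior
        double lt = 0.5 * std::log(tau2(k));
        double lt_new = lt + 0.35 * R::norm_rand();
        double ss = accu(square(theta_city.col(k) - theta_bar(k)));
        auto lpost = [&](double l) {
          double t2 = std::exp(2.0 * l);
          return -0.5 * M * std::log(t2) - 0.5 * ss / t2 -
            0.5 * t2 / (tau_sd * tau_sd) + l;  // + log|Jacobian|
        };
        if (std::log(R::unif_rand()) < lpost(lt_new) - lpost(lt))
          tau2(k) = std::exp(2.0 * lt_new);
      }
    }

    // store
    int post = it - n_burn;
    if (post >= 0 && (post + 1) % thin == 0 && saved < n_save) {
      if (random_effect) {
        save_theta.row(saved) = theta_bar.t();
        save_theta_city.row(saved) = vectorise(theta_city).t();
        save_tau2.row(saved) = tau2.t();
      } else {
        save_theta.row(saved) = beta_out.subvec(iT, iT + K - 1).t();
      }
      save_beta_out.row(saved) = beta_out.t();
      save_beta_a.row(saved) = vectorise(beta_a).t();
      if (p > 0) save_alpha_w.row(saved) = alpha_w.t();
      if (latent) save_alpha_wu.row(saved) = vectorise(alpha_wu).t();
      save_sigma(saved, 0) = sigma_y2;
      save_sigma(saved, 1) = sigma_z2;
      for (int k = 0; k < p; k++) save_sigma(saved, 2 + k) = sigma_w2(k);
      vec mu_y = X_out * beta_out + off;
      for (int j = 0; j < n; j++)
        save_loglik(saved, j) =
          R::dnorm(y(j), mu_y(j), std::sqrt(sigma_y2), 1);
      if (nU > 0) U_mean += U;
      saved++;
    }
  }
  if (nU > 0 && saved > 0) U_mean /= saved;

  if (!save_loglik.is_finite())
    Rcpp::stop("non-finite outcome log-likelihood: sampler diverged");

  return Rcpp::List::create(
    Rcpp::Named("theta") = save_theta,
    Rcpp::Named("theta_city") = save_theta_city,
    Rcpp::Named("tau2") = save_tau2,
    Rcpp::Named("beta_out") = save_beta_out,
    Rcpp::Named("beta_a") = save_beta_a,
    Rcpp::Named("alpha_w") = save_alpha_w,
    Rcpp::Named("alpha_wu") = save_alpha_wu,
    Rcpp::Named("sigma") = save_sigma,
    Rcpp::Named("loglik") = save_loglik,
    Rcpp::Named("U_mean") = U_mean,
    Rcpp::Named("n_saved") = saved,
    Rcpp::Named("layout") = Rcpp::List::create(
      Rcpp::Named("iT") = iT, Rcpp::Named("iU") = iU,
      Rcpp::Named("iW") = iW, Rcpp::Named("iZ") = has_z ? iZ : -1,
      Rcpp::Named("Pout") = Pout, Rcpp::Named("Pa") = Pa));
}
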