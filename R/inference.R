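#' MCMC fitting configuration
#'
#' Controls for the Gibbs sampler. The full-scale protocol is 50,000
#' burn-in / 50,000 retained iterations with thinning 10 and a single
#' chain; the defaults here are that protocol, but every replicated study
#' in this package's tests uses reduced desk-scale settings (documented
#' where used).
#'
#' @param variant `"latent_adjustment"` (the full structural model),
#'   `"outcome_regression_proxy"` (proxies as outcome covariates, latent
#'   factor dropped), or `"no_adjustment"` (latent factor and proxies both
#'   dropped). All variants keep the spatial spline process (at ratio > 0)
#'   and the probit treatment equation.
#' @param effect `"constant"` (one effect per treatment column) or
#'   `"random"` (per-city effects with a population mean and scale).
#' @param q latent confounder dimension (>= 1 for latent adjustment).
#' @param n_burn,n_keep,thin MCMC controls.
#' @param coef_sd normal prior SD for regression coefficients/intercepts.
#' @param ig_shape,ig_rate inverse-gamma prior for variances.
#' @param tau_sd half-normal prior scale for the random-effect SD tau.
#' @param seed integer RNG seed.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(variant = c("latent_adjustment",
                                   "outcome_regression_proxy",
                                   "no_adjustment"),
                       effect = c("constant", "random"),
                       q = 1,
                       n_burn = 50000, n_keep = 50000, thin = 10,
                       coef_sd = 10, ig_shape = 0.1, ig_rate = 0.1,
                       tau_sd = 5, seed = 1) {
  variant <- match.arg(variant)
  effect <- match.arg(effect)
  stopifnot(n_burn >= 1, n_keep >= 1, thin >= 1, n_keep %% thin == 0)
  if (variant == "latent_adjustment" && q < 1) {
    stop("latent_adjustment requires q >= 1")
  }
  structure(list(variant = variant, effect = effect, q = as.integer(q),
                 n_burn = as.integer(n_burn), n_keep = as.integer(n_keep),
                 thin = as.integer(thin),
                 coef_sd = coef_sd, ig_shape = ig_shape, ig_rate = ig_rate,
                 tau_sd = tau_sd, seed = as.integer(seed)),
            class = "fit_config")
}

variant_code <- function(variant) {
  match(variant, c("latent_adjustment", "outcome_regression_proxy",
                   "no_adjustment")) - 1L
}

#' Fit the spatial latent-factor causal model by Gibbs sampling
#'
#' Runs the probit-augmented Gibbs sampler for the requested variant and
#' returns thinned post-burn-in posterior draws, the pointwise outcome
#' log-likelihood matrix, and WAIC. Rows of `table` must be sorted by
#' (city, region), which [region_table()] guarantees.
#'
#' @param table a [region_table()].
#' @param bases named list of `basis_matrix` (one per city, all at the same
#'   ratio), or `NULL` for ratio 0 (no spatial term).
#' @param design a `treatment_design` from [encode_treatment()].
#' @param config a [fit_config()].
#' @param freeze optional named list used by oracle tests to hold parameter
#'   blocks at their initial values; see Details.
#' @param init optional named list of initial values overriding defaults
#'   (`beta_out`, `beta_a`, `alpha_w`, `alpha_wu`, `sigma_y2`, `sigma_w2`,
#'   `sigma_z2`, `U`, `theta_city`, `theta_bar`, `tau2`).
#'
#' @details `freeze` entries (all default to updating): `out_coef` — logical
#'   vector over the outcome coefficient vector (see the returned
#'   `layout`); `treat`, `w_intercept`, `sigma_y`, `sigma_w`, `sigma_z`,
#'   `lambda`, `u` — logical scalars; `w_load` — logical p x q matrix;
#'   `sign_identify` — apply the loading sign normalization (default TRUE
#'   for full latent fits, forced off when the treatment block is frozen).
#'
#' @return object of class `posterior_draws`: chains for the effect(s) and
#'   all structural parameters, `loglik` (draws x regions), `waic`, the
#'   outcome design `layout`, and the configuration.
#' @export
fit_model <- function(table, bases, design, config, freeze = list(),
                      init = list()) {
  y <- table$outcome
  n <- length(y)
  Tmat <- design$indicator
  K <- ncol(Tmat)
  p <- attr(table, "p")
  cities <- sort(unique(table$city))
  M <- length(cities)
  variant <- config$variant
  vcode <- variant_code(variant)
  latent <- variant == "latent_adjustment"
  q <- if (latent) config$q else 0L
  random_effect <- config$effect == "random"

  Wfull <- as.matrix(table[, paste0("w", seq_len(p)), drop = FALSE])
  Wpass <- if (vcode <= 1) Wfull else matrix(0, n, 0)
  p_pass <- ncol(Wpass)

  if (is.null(bases)) {
    B_list <- lapply(cities, function(ci) {
      matrix(0, sum(table$city == ci), 0)
    })
  } else {
    if (!setequal(names(bases), as.character(cities))) {
      stop("bases must be a named list covering exactly the table's cities")
    }
    B_list <- lapply(as.character(cities), function(ci) bases[[ci]]$B)
    nb <- sapply(B_list, nrow)
    if (!all(nb == as.vector(table(table$city)[as.character(cities)]))) {
      stop("basis rows do not match region counts per city")
    }
  }
  Ltot <- sum(sapply(B_list, ncol))
  has_z <- Ltot > 0

  nT <- if (random_effect) 0L else K
  nU <- if (latent) q else 0L
  nW <- if (vcode == 1) p else 0L
  Pout <- 1L + nT + nU + nW + as.integer(has_z)
  Pa <- 1L + (if (latent) q else 0L) + as.integer(has_z)

  defaults <- list(
    beta_out = numeric(Pout),
    beta_a = matrix(0, Pa, K),
    alpha_w = numeric(max(p_pass, 0)),
    alpha_wu = if (latent) matrix(0.5, p, q) else NULL,
    sigma_y2 = 1, sigma_w2 = rep(1, max(p_pass, 0)), sigma_z2 = 1,
    U = if (latent) matrix(0, n, q) else NULL,
    theta_city = matrix(0, M, K), theta_bar = numeric(K),
    tau2 = rep(1, K))
  for (nm in names(init)) defaults[[nm]] <- init[[nm]]
  ini <- defaults

  frz <- function(nm, default) {
    if (is.null(freeze[[nm]])) default else freeze[[nm]]
  }
  out_free <- frz("out_coef", rep(TRUE, Pout))
  if (length(out_free) != Pout) stop("freeze$out_coef has wrong length")
  upd_treat <- frz("treat", TRUE)
  upd <- list(
    free_out = as.integer(which(out_free) - 1L),
    treat = upd_treat,
    w_intercept = frz("w_intercept", TRUE),
    w_load = if (latent) {
      wl <- frz("w_load", matrix(TRUE, p, q))
      matrix(as.numeric(wl), p, q)
    } else matrix(0, 0, 0),
    sigma_y = frz("sigma_y", TRUE),
    sigma_w = frz("sigma_w", TRUE),
    sigma_z = frz("sigma_z", TRUE),
    lambda = frz("lambda", TRUE),
    u = frz("u", TRUE),
    sign_identify = frz("sign_identify", latent && upd_treat))

  set.seed(config$seed)
  res <- gibbs_fit_cpp(y, Tmat, Wpass, as.integer(table$city) - 1L,
                       B_list, vcode, q, random_effect,
                       config$n_burn, config$n_keep, config$thin,
                       config$coef_sd, config$ig_shape, config$ig_rate,
                       config$tau_sd, ini, upd)

  colnames(res$theta) <- colnames(Tmat)
  draws <- structure(list(
    theta = res$theta,
    theta_city = if (random_effect) res$theta_city else NULL,
    tau2 = if (random_effect) res$tau2 else NULL,
    beta_out = res$beta_out,
    beta_a = res$beta_a,
    alpha_w = res$alpha_w,
    alpha_wu = res$alpha_wu,
    sigma = res$sigma,
    loglik = res$loglik,
    U_mean = res$U_mean,
    layout = res$layout,
    effect_names = colnames(Tmat),
    cities = cities,
    variant = variant,
    config = config,
    ratio = if (is.null(bases)) 0 else bases[[1]]$ratio),
    class = "posterior_draws")
  draws$waic <- waic(draws)
  draws
}

#' Watanabe-Akaike information criterion of the outcome model
#'
#' `WAIC = -2 (lppd - p_WAIC)` with
#' `lppd = sum_j log mean_d p(y_j | draw d)` and
#' `p_WAIC = sum_j var_d log p(y_j | draw d)`, computed from the pointwise
#' outcome log-likelihood matrix only (the treatment and proxy equations do
#' not enter).
#'
#' @param draws a `posterior_draws` object, or a draws x regions pointwise
#'   log-likelihood matrix.
#' @return scalar WAIC.
#' @export
waic <- function(draws) {
  ll <- if (inherits(draws, "posterior_draws")) draws$loglik else draws
  if (nrow(ll) < 2) stop("need at least 2 draws to compute WAIC")
  ndraw <- nrow(ll)
  # column-wise log-sum-exp for lppd
  mx <- apply(ll, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(ll, 2, mx)))))
  p_waic <- sum(apply(ll, 2, stats::var))
  -2 * (lppd - p_waic)
}

#' Posterior summary of the treatment effect(s)
#'
#' Posterior mean and equal-tailed credible interval for each treatment
#' effect; in random-effect mode also per-city effects and the population
#' mean.
#'
#' @param draws a `posterior_draws`.
#' @param level credible level (default 0.95).
#' @return data.frame with columns `effect`, `mean`, `ci_low`, `ci_high`
#'   (random-effect fits gain a `city` column, with `NA` for the
#'   population-mean rows).
#' @export
ate_summary <- function(draws, level = 0.95) {
  a <- (1 - level) / 2
  summ <- function(x) c(mean = mean(x),
                        ci_low = unname(stats::quantile(x, a)),
                        ci_high = unname(stats::quantile(x, 1 - a)))
  th <- draws$theta
  out <- data.frame(effect = colnames(th),
                    t(apply(th, 2, summ)), row.names = NULL)
  if (!is.null(draws$theta_city)) {
    out$city <- NA_integer_
    M <- length(draws$cities)
    K <- ncol(th)
    rows <- lapply(seq_len(M * K), function(j) {
      k <- (j - 1) %/% M + 1
      i <- (j - 1) %% M + 1
      s <- summ(draws$theta_city[, j])
      data.frame(effect = colnames(th)[k], mean = s["mean"],
                 ci_low = s["ci_low"], ci_high = s["ci_high"],
                 city = draws$cities[i], row.names = NULL)
    })
    out <- rbind(out, do.call(rbind, rows))
  }
  out
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws: %s (%s effect), %d draws, ratio %.2f, WAIC %.1f\n",
              x$variant, x$config$effect, nrow(x$theta), x$ratio, x$waic))
  print(ate_summary(x))
  invisible(x)
}

#' Numeric check of the row-deletion factor identification condition
#'
#' For `Lambda = alpha_wu %*% sqrtm(Sigma)` (p x q): after deleting any
#' single row, there must exist a partition of the remaining rows into two
#' disjoint submatrices each of numerical rank q (Anderson-Rubin). The
#' search enumerates row partitions; numerical rank uses a singular-value
#' tolerance.
#'
#' @param alpha_wu p x q loading matrix.
#' @param Sigma q x q (conditional) covariance of the latent confounder.
#' @param tol singular values below `tol * max(sv)` count as zero.
#' @return list with `satisfied` (logical) and `detail` (character).
#' @export
check_assumption5 <- function(alpha_wu, Sigma = diag(ncol(alpha_wu)),
                              tol = 1e-8) {
  alpha_wu <- as.matrix(alpha_wu)
  p <- nrow(alpha_wu)
  q <- ncol(alpha_wu)
  es <- eigen(Sigma, symmetric = TRUE)
  Lambda <- alpha_wu %*% (es$vectors %*% diag(sqrt(pmax(es$values, 0)),
                                              q) %*% t(es$vectors))
  if (p < 2 * q + 1) {
    return(list(satisfied = FALSE,
                detail = sprintf("p = %d < 2q + 1 = %d: unsatisfiable",
                                 p, 2 * q + 1)))
  }
  num_rank <- function(Mx) {
    if (nrow(Mx) < q) return(0L)
    sv <- svd(Mx, nu = 0, nv = 0)$d
    sum(sv > tol * max(sv, tol))
  }
  for (drop_row in seq_len(p)) {
    rest <- Lambda[-drop_row, , drop = FALSE]
    m <- nrow(rest)
    found <- FALSE
    # enumerate subsets of size q..m-q for the first group
    for (mask in seq_len(2^m - 2)) {
      g1 <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
      if (length(g1) < q || m - length(g1) < q) next
      if (num_rank(rest[g1, , drop = FALSE]) == q &&
          num_rank(rest[-g1, , drop = FALSE]) == q) {
        found <- TRUE
        break
      }
    }
    if (!found) {
      return(list(satisfied = FALSE,
                  detail = sprintf(
                    "deleting row %d leaves no rank-%d/rank-%d split",
                    drop_row, q, q)))
    }
  }
  list(satisfied = TRUE,
       detail = sprintf("all %d single-row deletions admit a rank-%d split",
                        p, q))
}

#' Split-Rhat convergence diagnostic for a single chain
#'
#' Splits the chain in half and computes the usual potential scale reduction
#' factor; values near 1 indicate the two halves agree.
#'
#' @param x numeric vector of draws.
#' @return scalar Rhat.
#' @export
split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  halves <- cbind(x[seq_len(n)], x[n + seq_len(n)])
  m <- ncol(halves)
  bm <- colMeans(halves)
  B <- n * stats::var(bm)
  Wv <- mean(apply(halves, 2, stats::var))
  sqrt(((n - 1) / n * Wv + B / n) / Wv)
}
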