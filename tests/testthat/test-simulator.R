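poly_area <- function(poly) {
  r <- spcausal:::close_ring(unclass(poly)[[1]])
  abs(sum(r[-nrow(r), 1] * r[-1, 2] - r[-1, 1] * r[-nrow(r), 2])) / 2
}

test_that("grid cities tile as specified", {
  geom <- make_grid_cities(10, 7)
  expect_length(geom, 10)
  expect_equal(sum(sapply(geom, function(g) length(g$polys))), 490)

  g1 <- make_grid_cities(1, 2)[[1]]
  expect_length(g1$polys, 4)
  expect_equal(unname(spcausal:::polygons_bbox(g1$polys)), c(0, 0, 2, 2))
  expect_true(all(sapply(g1$polys, poly_area) == 1))
  expect_true(all(sapply(geom[[3]]$polys, poly_area) == 1))

  expect_error(make_grid_cities(0, 7), "M")
  expect_error(make_grid_cities(2, 1), "grid_dim")
})

test_that("presets differ from base only in the named aspect", {
  base <- scenario_preset("base")
  expect_equal(base$q, 1)
  expect_equal(base$p, 3)
  expect_equal(base$theta, 1)
  expect_equal(base$r_true, 0.4)
  expect_equal(scenario_preset("rough_spatial")$r_true, 0.6)

  differs_only_in <- function(a, b, fields) {
    nm <- names(a)
    same <- setdiff(nm, fields)
    all(sapply(same, function(f) identical(a[[f]], b[[f]]))) &&
      all(sapply(fields, function(f) !identical(a[[f]], b[[f]])))
  }
  expect_true(differs_only_in(base, scenario_preset("noisy_outcome"),
                              "sigma_y2"))
  expect_true(differs_only_in(base, scenario_preset("strong_proxy"),
                              "alpha_wu"))
  expect_true(differs_only_in(base, scenario_preset("weak_proxy"),
                              "alpha_wu"))
  expect_true(differs_only_in(base, scenario_preset("rough_spatial"),
                              "r_true"))
  expect_true(differs_only_in(base, scenario_preset("strong_confounding"),
                              c("alpha_yu", "alpha_au")))
  expect_error(scenario_preset("nope"))

  # every preset's loading matrix passes the identification diagnostic
  for (nm in c("base", "strong_proxy", "noisy_outcome", "rough_spatial",
               "weak_proxy", "strong_confounding")) {
    cfg <- scenario_preset(nm)
    expect_true(check_assumption5(cfg$alpha_wu, diag(cfg$q))$satisfied,
                label = nm)
  }
})

test_that("degenerate limit: zero noise, zero alphas gives Y == A == 0", {
  cfg <- scenario_config(M = 1, grid_dim = 3, theta = 1,
                         alpha_yu = 0, alpha_au = 0,
                         alpha_wu = matrix(0, 3, 1),
                         alpha_yz = 0, alpha_az = 0,
                         sigma_y2 = 0, sigma_a2 = 0, sigma_w2 = rep(0, 3),
                         sigma_z2 = 0, check_identification = FALSE)
  sim <- simulate_dataset(cfg, seed = 1)
  expect_true(all(sim$table$treatment == 0))  # I(0 > 0) is FALSE
  expect_true(all(sim$table$outcome == 0))
})

test_that("seed determinism: identical seeds reproduce bit-identically", {
  cfg <- tiny_scenario()
  geom <- make_grid_cities(cfg$M, cfg$grid_dim)
  s1 <- simulate_dataset(cfg, geom, seed = 77)
  s2 <- simulate_dataset(cfg, geom, seed = 77)
  expect_identical(s1$table$outcome, s2$table$outcome)
  expect_identical(s1$truth$lambda, s2$truth$lambda)
  s3 <- simulate_dataset(cfg, geom, seed = 78)
  expect_false(identical(s1$table$outcome, s3$table$outcome))
})

test_that("treated fraction is ~1/2 with a symmetric treatment index", {
  cfg <- scenario_config(M = 10, grid_dim = 7, alpha_a = 0,
                         alpha_au = 0, alpha_az = 0, r_true = 0,
                         check_identification = TRUE)
  geom <- make_grid_cities(10, 7)
  fr <- sapply(1:50, function(t) {
    mean(simulate_dataset(cfg, geom, seed = 1000 + t)$table$treatment)
  })
  expect_lt(abs(mean(fr) - 0.5), 0.03)
})

test_that("simulated moments match the factor-model identities", {
  # r_true = 0 so Y = theta A + a_yu U + eps_y, A = I(a_au U + eps_a > 0)
  cfg <- scenario_config(M = 100, grid_dim = 7, r_true = 0)
  geom <- make_grid_cities(100, 7)
  sim <- simulate_dataset(cfg, geom, seed = 314)   # n = 4900
  W <- as.matrix(sim$table[, c("w1", "w2", "w3")])
  S <- cov(W)
  target <- cfg$alpha_wu %*% t(cfg$alpha_wu) + diag(cfg$sigma_w2)
  # elementwise MC standard error of a covariance at n = 4900 is ~0.03
  expect_lt(max(abs(S - target)), 3 * 0.03)

  # var(Y) closed form: theta^2 p(1-p) + a_yu^2 + sig_y2
  #                     + 2 theta a_yu E[U 1(idx > 0)]
  A <- sim$table$treatment
  idx_sd <- sqrt(cfg$alpha_au^2 + cfg$sigma_a2)
  cov_AU <- cfg$alpha_au / idx_sd * stats::dnorm(0)    # E[U 1(idx>0)]
  vy <- cfg$theta^2 * 0.25 + cfg$alpha_yu^2 + cfg$sigma_y2 +
    2 * cfg$theta * cfg$alpha_yu * cov_AU
  expect_lt(abs(var(sim$table$outcome) - vy) / vy, 0.1)
})

test_that("without confounding the raw mean difference is unbiased", {
  cfg <- scenario_config(M = 4, grid_dim = 5, q = 1, theta = 1,
                         alpha_yu = 0, alpha_au = 0,
                         alpha_az = 0, r_true = 0,
                         alpha_wu = matrix(0, 3, 1),
                         check_identification = FALSE)
  geom <- make_grid_cities(4, 5)
  diffs <- sapply(1:40, function(t) {
    tab <- simulate_dataset(cfg, geom, seed = 2000 + t)$table
    mean(tab$outcome[tab$treatment == 1]) -
      mean(tab$outcome[tab$treatment == 0])
  })
  # MC standard error ~ sd/sqrt(40)
  expect_lt(abs(mean(diffs) - 1), 3 * sd(diffs) / sqrt(40))
})

test_that("scaled-t latents keep the stated variance", {
  cfg <- scenario_config(M = 20, grid_dim = 7, r_true = 0,
                         dist_u = "t", df_u = 5)
  sim <- simulate_dataset(cfg, seed = 88)
  # var(U) = 1 by construction regardless of distribution family
  expect_lt(abs(var(sim$truth$U[, 1]) - 1), 0.15)
  # heavier tails than Gaussian at df = 5
  expect_gt(mean(sim$truth$U^4), 3 * var(sim$truth$U)^2)
  expect_error(scenario_config(dist_u = "t", df_u = 2) |>
                 simulate_dataset(seed = 1), "df > 2")
})

test_that("multilevel generator: boundaries, exclusivity, shares", {
  cfg <- scenario_config(M = 2, grid_dim = 5, theta = c(0.5, 1, 1.5),
                         alpha_a = -100)
  sim <- simulate_multilevel(cfg, seed = 4)
  expect_true(all(sim$table$treatment == "A"))  # indices forced negative

  cfg2 <- scenario_config(M = 10, grid_dim = 7, theta = c(0.5, 1, 1.5))
  sim2 <- simulate_multilevel(cfg2, seed = 9)
  expect_true(all(sim2$table$treatment %in% c("A", "B", "C", "D")))
  des <- encode_treatment(sim2$table, "multilevel")
  expect_true(all(rowSums(des$indicator) <= 1))

  # cutpoints at quartiles of the (approximate) index scale give roughly
  # equal shares when the index parameters are symmetric
  shares <- table(factor(sim2$table$treatment,
                         levels = c("A", "B", "C", "D"))) / 490
  expect_true(all(shares > 0.10 & shares < 0.45))
})
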