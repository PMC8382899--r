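# Normal-approximation error theory and covariance machinery.

pb_hard <- marginal_pattern_probs(p_hard)$pbar

test_that("the normal approximation reproduces its pinned reference cells", {
  # three independent reproductions pin the numerator/denominator convention
  expect_equal(round(zeta_multinomial(1000, pb_hard[2], pb_hard[3]), 3), 0.644)
  expect_equal(round(zeta_multinomial(1000, 0.33273, 0.30811), 3), 0.264)
  g <- gene_tree_topology_probs(p_hard)
  expect_equal(round(zeta_multinomial(1000, g[1], g[2]), 3), 0.113)

  # multinomial form is the stated reduction of the general form
  withr::with_seed(31, {
    for (i in 1:25) {
      q2 <- runif(1, 0.05, 0.3)
      q1 <- q2 + runif(1, 1e-4, min(0.3, 1 - 2 * q2 - q2) - 0)
      m <- sample(10:5000, 1)
      cv <- coaltrio:::multinomial_cov(q1, q2)
      expect_equal(zeta_multinomial(m, q1, q2),
                   zeta_normal(m, q1 - q2, cv$sigma1_sq, cv$sigma2_sq,
                               cv$sigma12, cv$sigma23), tolerance = 1e-12)
    }
  })

  # limits: overwhelming signal, and the zero-signal uncorrelated case
  expect_lt(zeta_normal(100, 10, 1, 1, 0, 0), 1e-12)
  v <- pnorm(sqrt(1 / pi) / sqrt(2 - 1 / pi))
  for (m in c(3, 3000))
    expect_equal(zeta_normal(m, 0, 0.4, 0.4, 0, 0), v, tolerance = 1e-12)
  expect_equal(v, 0.66824, tolerance = 1e-4)

  expect_error(zeta_normal(10, 0.1, 1, 1, 0.99, -0.99),
               class = "coaltrio_domain_error")
  expect_error(zeta_multinomial(10, 0.2, 0.5), class = "coaltrio_domain_error")
})

test_that("the discontinuity-corrected variant stays behind its experimental flag", {
  expect_error(zeta_zly(1000, 0.3, 0.25), class = "coaltrio_domain_error")
  na_val <- zeta_zly(1000, pb_hard[2], pb_hard[3], experimental = TRUE)
  expect_true(is.na(na_val))
  expect_true(attr(na_val, "inapplicable"))
  ok <- zeta_zly(1e6, 0.36, 0.32, experimental = TRUE)
  expect_true(is.finite(ok) && ok >= 0 && ok <= 1)
})

test_that("Theorem-1 bound quantities match the reference table at n = infinity", {
  g <- gene_tree_topology_probs(p_hard)
  cv <- coaltrio:::multinomial_cov(g[1], g[2])
  b <- zeta_bounds(1000, g[1] - g[2], cv$sigma1_sq, cv$sigma2_sq,
                   cv$sigma12, cv$sigma23)
  expect_equal(b$a, 0.555962, tolerance = 5e-7)
  expect_equal(b$b, 1.72268, tolerance = 5e-5)
  expect_equal(round(b$lower, 3), 0.087)
  expect_equal(round(b$upper, 3), 0.132)
  # equality case at no signal
  b0 <- zeta_bounds(1000, 0, cv$sigma1_sq, cv$sigma2_sq, cv$sigma12,
                    cv$sigma23)
  expect_equal(b0$lower, 0.5 * (1 + 2 / pi * atan(b0$a)), tolerance = 1e-12)
  expect_equal(b0$upper, 1)
})

test_that("one-site covariance matches the multinomial identities and simulation", {
  S <- sigma_one_site(pb_hard)
  q <- pb_hard[2:4]
  expect_equal(diag(S), q * (1 - q), ignore_attr = TRUE)
  expect_equal(S[1, 2], -q[1] * q[2], ignore_attr = TRUE)
  expect_true(isSymmetric(S))

  d <- sim_dataset(p_hard, m = 2e5, n = 1, seed = 61)
  F <- as.matrix(d[, 3:5])
  Semp <- cov(F)
  se <- sqrt(2 / nrow(F)) * (abs(S) + mean(diag(S)))  # rough moment SE scale
  expect_true(all(abs(Semp - S) < 4 * se + 4e-4))
})

test_that("the infinite-sites covariance reproduces the marginal means and the zetaN cells", {
  SInf <- sigma_infinite(p_hard, R = 4e5, seed = 71)
  mu <- attr(SInf, "mean")
  expect_true(all(abs(mu - pb_hard[2:4]) < 4 * attr(SInf, "mc_se") + 1e-6))
  expect_true(all(diag(SInf) > 0))

  cv <- coaltrio:::exchangeable_cov(SInf)
  dmu <- unname(pb_hard[2] - pb_hard[3])
  zN <- zeta_normal(1000, dmu, cv$sigma1_sq, cv$sigma2_sq, cv$sigma12,
                    cv$sigma23)
  zN0 <- zeta_normal(1000, dmu, cv$sigma1_sq, cv$sigma2_sq, 0, 0)
  expect_equal(zN, 0.194, tolerance = 0.012)
  expect_equal(zN0, 0.166, tolerance = 0.012)
  # correlation between informative-pattern probabilities across loci
  rho <- cv$sigma12 / sqrt(cv$sigma1_sq * cv$sigma2_sq)
  expect_equal(rho, -0.181, tolerance = 0.01)
})

test_that("the mixed-n covariance interpolates and matches simulated per-locus frequencies", {
  S1 <- sigma_one_site(pb_hard)
  SInf <- sigma_infinite(p_hard, R = 4e5, seed = 81)
  expect_identical(sigma_mixed(S1, SInf, 1), S1[1:3, 1:3])
  expect_identical(sigma_mixed(S1, SInf, Inf), SInf[1:3, 1:3])
  Sn <- sigma_mixed(S1, SInf, 1000)
  expect_equal(Sn, (1 / 1000) * S1[1:3, 1:3] + (999 / 1000) * SInf[1:3, 1:3])

  d <- sim_dataset(p_hard, m = 3e4, n = 1000, seed = 82)
  F <- as.matrix(d[, 3:5]) / 1000
  Semp <- cov(F)
  se <- sqrt(2 / nrow(F)) * (abs(Sn) + mean(diag(Sn)))
  expect_true(all(abs(Semp - Sn) < 4 * se + 1e-6))
  expect_error(sigma_mixed(S1, SInf, 0), class = "coaltrio_domain_error")
})

test_that("gene-tree recovery probabilities are exact at the ends and match the printed MC values", {
  r1 <- gene_tree_recovery(p_hard, 1)
  expect_equal(r1$g1, unname(pb_hard[2]))
  expect_equal(r1$g2, unname(pb_hard[3]))
  expect_equal(round(r1$p_tie, 5), 0.92948)
  expect_identical(r1$mode, "exact-n1")

  ri <- gene_tree_recovery(p_hard, Inf)
  expect_equal(ri$g1, 0.3594737, tolerance = 1e-7)
  expect_identical(ri$p_tie, 0)

  rn <- gene_tree_recovery(p_hard, 1000, R = 1e5, seed = 91)
  expect_lt(abs(rn$g1 - 0.33273), 4 * rn$mc_se[1])
  expect_lt(abs(rn$g2 - 0.30811), 4 * rn$mc_se[2])
  expect_lt(abs(rn$g2 - rn$g3), 4 * sqrt(rn$mc_se[2]^2 + rn$mc_se[3]^2))
  expect_lt(rn$g1, ri$g1)  # phylogenetic error: g1(n) < P(G1)
  expect_equal(rn$g1 + rn$g2 + rn$g3 + rn$p_tie, 1, tolerance = 1e-12)
})

test_that("method-specific error predictors reproduce the reference cells and track simulation", {
  expect_equal(round(predict_two_step_error(p_hard, 1000, Inf)$value, 3),
               0.113)
  expect_equal(round(predict_two_step_error(p_hard, 1000, 1)$value, 3), 0.644)

  pred <- predict_two_step_error(p_hard, 1000, 1000, R = 1e5, seed = 92)
  sim <- run_error_experiment(p_hard, "two_step", 1000, 1000, R = 4e3,
                              seed = 93)
  expect_lt(abs(pred$value - sim$error), 0.01 + 4 * sim$mc_se)

  # isml: n = 1 coincides with two-step; n = infinity matches its cell
  p1 <- predict_isml_error(p_hard, 1000, 1)
  expect_equal(p1$value, predict_two_step_error(p_hard, 1000, 1)$value,
               tolerance = 1e-12)
  pi_inf <- predict_isml_error(p_hard, 1000, Inf, R = 4e5, seed = 94)
  expect_equal(pi_inf$value, 0.194, tolerance = 0.012)
  sim_i <- run_error_experiment(p_hard, "isml", 1000, Inf, R = 5e3, seed = 95)
  expect_lt(abs(pi_inf$value - sim_i$error), 0.002 + 4 * sim_i$mc_se)
})

test_that("the exact infinite-sites ML error law evaluates correctly", {
  expect_equal(round(ml_error_infinite_n(p_hard, 10)$value, 2), 0.45)
  expect_equal(round(ml_error_infinite_n(p_hard, 100)$value, 2), 0.01)
  expect_equal(ml_error_infinite_n(p_hard, 0)$value, 2 / 3)
  expect_equal(ml_error_infinite_n(p_hard, 10)$value,
               p_hard$phi^10 * 2 / 3, tolerance = 1e-15)
})

test_that("predicted errors are affine in sqrt(m) on the probit scale", {
  ms <- c(10, 20, 50, 100, 200, 500, 1000)
  g <- gene_tree_topology_probs(p_hard)
  df <- tibble::tibble(m = ms,
                       error = vapply(ms, function(m)
                         zeta_multinomial(m, g[1], g[2]), numeric(1)))
  fit <- probit_linearity(df)
  expect_gt(fit$r_squared, 1 - 1e-6)
  expect_lt(fit$slope, 0)
})

test_that("the KL-divergence predictor is coherent and tracks direct ML simulation", {
  kl <- kl_predict_ml_error(p_hard, n = 2, m = 50, R_ref = 1500, seed = 96,
                            quad_nodes = 12)
  expect_gte(kl$kl$D12, 0)
  expect_gte(kl$kl$D13, 0)
  expect_true(kl$value >= 0 && kl$value <= 1)

  sim <- run_error_experiment(p_hard, "ml", m = 50, n = 2, R = 60, seed = 97,
                              quad_nodes = 12, n_starts = 1)
  expect_lt(abs(kl$value - sim$error), 3 * sim$mc_se + 0.02)
})
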