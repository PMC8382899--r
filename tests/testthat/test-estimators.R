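# Summary species-tree estimators and parameter estimation.

test_that("the count rule recovers the ML gene tree", {
  expect_identical(ml_gene_tree(c(0, 5, 3, 2, 0))$tie, 1L)
  expect_identical(ml_gene_tree(c(0, 4, 4, 1, 1))$tie, c(1L, 2L))
  expect_identical(ml_gene_tree(c(3, 0, 0, 0, 0))$tie, 1:3)

  # numeric JC-clock ML over the three rooted gene trees (grid oracle)
  grid_oracle <- function(x) {
    tg <- exp(seq(log(1e-4), log(0.5), length.out = 60))
    best <- sapply(1:3, function(tr) {
      xp <- x[coaltrio:::tree_count_perm(tr)]
      mx <- -Inf
      for (t1 in tg) {
        P <- pattern_probs(pmax(tg, t1), rep(t1, length(tg)))
        ll <- as.vector(log(pmax(P, 1e-300)) %*% xp)
        mx <- max(mx, ll)
      }
      mx
    })
    which(best >= max(best) - 1e-9)
  }
  withr::with_seed(12, {
    for (i in 1:60) {
      x <- as.vector(rmultinom(1, sample(5:40, 1),
                               pattern_probs(runif(1, 0.01, 0.1),
                                             runif(1, 0.001, 0.01))[1, ]))
      counts_call <- ml_gene_tree(x)$tie
      if (length(counts_call) == 1)  # strict maxima only: ties depend on grid
        expect_identical(grid_oracle(x), counts_call)
    }
  })
})

test_that("two-step and pooled-count calls reproduce the worked three-locus examples", {
  # loci with site patterns "11", "02", "00" (n = 2)
  d1 <- rbind(c(0, 2, 0, 0, 0), c(1, 0, 1, 0, 0), c(2, 0, 0, 0, 0))
  colnames(d1) <- c("xxx", "xxy", "yxx", "xyx", "xyz")
  ts <- two_step(d1)
  expect_identical(ts$tie, c(1L, 2L))
  expect_equal(unname(ts$support[1] - ts$support[2]), 0)
  cc <- concat_isml_topology(d1)
  expect_identical(cc$tie, 1L)
  expect_equal(unname(cc$support), c(2, 1, 0))

  # loci "33", "01", "14"
  d2 <- rbind(c(0, 0, 0, 2, 0), c(1, 1, 0, 0, 0), c(0, 1, 0, 0, 1))
  colnames(d2) <- colnames(d1)
  ts2 <- two_step(d2)
  expect_identical(ts2$tie, 1L)
  expect_equal(unname(ts2$support), c(2, 0, 1))
  cc2 <- concat_isml_topology(d2)
  expect_identical(cc2$tie, c(1L, 3L))

  # pure supporting pattern
  pure <- matrix(rep(c(0, 5, 0, 0, 0), 4), 4, byrow = TRUE,
                 dimnames = list(NULL, colnames(d1)))
  expect_identical(two_step(pure)$tie, 1L)

  # tie policies: drop removes tied loci from the tallies
  tsd <- two_step(d1, tie_policy = "drop")
  expect_equal(unname(tsd$support), c(1, 1, 0))
  withr::with_seed(5, {
    tsr <- two_step(d1, tie_policy = "random")
    expect_equal(sum(tsr$support), 3)
  })
  expect_equal(sum(two_step(d1)$support), 3)  # even credit conserves votes
})

test_that("tidy methods expose calls as tibbles", {
  d <- sim_dataset(p_hard, m = 30, n = 20, seed = 3)
  td <- tidy(two_step(d))
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 3L)
  expect_true(any(td$winner))
})

test_that("the infinite-sites ML rule follows the smallest coalescent time and the exact error law", {
  gt <- sim_gene_trees(p_hard, m = 50, seed = 8)
  call <- species_tree_from_true_gene_trees(gt)
  expect_identical(call$winner, 1L)  # contains G1a loci almost surely

  gt1 <- tibble::tibble(topology = 2L, t1 = 0.03, t0 = 0.05)
  expect_identical(species_tree_from_true_gene_trees(gt1)$winner, 2L)

  # error frequency matches phi^m * 2/3 for several m
  for (m in c(1, 5, 20)) {
    est <- run_error_experiment(p_hard, "ml", m = m, n = Inf, R = 2e4,
                                seed = 100 + m)
    truth <- ml_error_infinite_n(p_hard, m)$value
    expect_lt(abs(est$error - truth),
              3 * sqrt(truth * (1 - truth) / 2e4))
  }
})

test_that("concatenation node-age MLEs are exact at the truth and biased under the MSC", {
  x <- 1e7 * pattern_probs(0.03, 0.02)[1, ]
  fit <- concat_fit_times(x)
  expect_lt(abs(fit$t0_hat - 0.03), 1e-8)
  expect_lt(abs(fit$t1_hat - 0.02), 1e-8)

  expect_warning(fit0 <- concat_fit_times(c(100, 0, 0, 0, 0)))
  expect_identical(c(fit0$t0_hat, fit0$t1_hat), c(0, 0))

  # m -> infinity pseudotrue fit: maximize against the exact marginal; the
  # result must beat a fine grid (KL-divergence minimization oracle)
  pb <- marginal_pattern_probs(p_bias)$pbar
  fit_inf <- concat_fit_times(1e9 * pb)
  tg <- seq(0.005, 0.05, length.out = 120)
  grid_best <- -Inf
  for (t1 in tg) {
    P <- pattern_probs(pmax(tg, t1), rep(t1, length(tg)))
    grid_best <- max(grid_best, max(as.vector(log(P) %*% (1e9 * pb))))
  }
  expect_gte(fit_inf$loglik, grid_best - 1e-7 * abs(grid_best))
  # the bias documented for this setting: ages overshoot the true (0.02, 0.01)
  expect_gt(fit_inf$t0_hat, 0.025)
  expect_gt(fit_inf$t1_hat, 0.012)
})

test_that("isml moment inversion is exact at the truth and fails gracefully", {
  pb <- marginal_pattern_probs_equal_theta(0.02, 0.01, 0.02)$pbar
  est <- isml_estimate_params(pb)
  expect_equal(est$theta_hat, 0.02, tolerance = 1e-10)
  expect_equal(est$tau0_hat, 0.02, tolerance = 1e-10)
  expect_equal(est$tau1_hat, 0.01, tolerance = 1e-10)

  expect_error(isml_estimate_params(c(1, 3, 3, 3, 6) / 16),
               class = "coaltrio_estimation_error")

  # theta0 != theta1 truth: finite estimates that do not recover the truth
  pb2 <- marginal_pattern_probs(p_hard)$pbar
  est2 <- isml_estimate_params(pb2)
  expect_true(is.finite(est2$theta_hat) && est2$theta_hat > 0)
  expect_gt(abs(est2$tau1_hat - p_hard$tau1), 1e-4)
  expect_gt(abs(est2$theta_hat - p_hard$theta1), 1e-4)

  # round trip across random equal-theta parameter draws
  for (pp in random_params(20, seed = 9)) {
    pbe <- marginal_pattern_probs_equal_theta(pp$tau0, pp$tau1, pp$theta0)$pbar
    e <- isml_estimate_params(pbe)
    expect_equal(e$theta_hat, pp$theta0, tolerance = 1e-7)
    expect_equal(e$tau0_hat, pp$tau0, tolerance = 1e-7)
    expect_equal(e$tau1_hat, pp$tau1, tolerance = 1e-7)
  }
})

test_that("the pooled-count argmax equals maximized pooled-likelihood model choice", {
  # direct optimization of the pooled multinomial likelihood over the
  # marginal-model parameter space, per candidate tree
  max_pooled_ll <- function(x, tree) {
    xp <- x[coaltrio:::tree_count_perm(tree)]
    nll <- function(par) {
      e <- pmin(pmax(exp(par), 1e-9), 5)
      pb <- marginal_pattern_probs(msc_params(e[1] + e[2], e[1], e[3],
                                              e[4]))$pbar
      -sum(xp * log(pmax(pb, 1e-300)))
    }
    best <- Inf
    for (s in list(log(c(0.01, 0.01, 0.02, 0.02)),
                   log(c(0.03, 0.03, 0.05, 0.05)),
                   log(c(0.005, 0.002, 0.01, 0.08)))) {
      f <- optim(s, nll, method = "Nelder-Mead",
                 control = list(maxit = 800, reltol = 1e-12))
      best <- min(best, f$value)
    }
    -best
  }
  withr::with_seed(17, {
    n_checked <- 0
    while (n_checked < 200) {
      x <- as.vector(rmultinom(1, 12, c(0.5, 0.2, 0.12, 0.12, 0.06)))
      call <- coaltrio:::argmax_call(x[2:4])
      if (length(call$tie) > 1) next  # strict maxima pin the theorem's claim
      lls <- vapply(1:3, function(tr) max_pooled_ll(x, tr), numeric(1))
      expect_identical(which.max(lls), as.integer(call$winner))
      n_checked <- n_checked + 1
    }
  })
})
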