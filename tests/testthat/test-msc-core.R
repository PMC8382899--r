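# Closed-form probability machinery of the MSC + JC triplet model.

test_that("non-coalescence probability and topology probabilities match closed forms", {
  expect_equal(noncoalescence_prob(p_hard), exp(-0.04), tolerance = 1e-12)
  expect_equal(noncoalescence_prob(msc_params(0.02, 0.02, 0.01, 0.05)), 1)
  expect_lt(noncoalescence_prob(msc_params(0.5, 0.001, 0.01, 0.001)), 1e-100)

  g <- gene_tree_topology_probs(p_hard)
  expect_equal(unname(g), c(0.3594737, 0.3202631, 0.3202631), tolerance = 2e-7)
  expect_equal(sum(g), 1, tolerance = 1e-12)
  expect_equal(unname(gene_tree_topology_probs(msc_params(0.02, 0.02, 1, 1))),
               rep(1 / 3, 3))
  g_far <- gene_tree_topology_probs(msc_params(0.5, 0.001, 0.01, 0.001))
  expect_equal(unname(g_far), c(1, 0, 0), tolerance = 1e-12)

  expect_error(msc_params(0.01, 0.02, 0.01, 0.05), class = "coaltrio_domain_error")
  expect_error(msc_params(0.02, 0.01, -1, 0.05), class = "coaltrio_domain_error")
})

test_that("the MSC density integrates to the class masses and to 1", {
  p <- p_hard
  expect_identical(msc_density("G1a", p$tau1 - 1e-6, p$tau0 + 0.01, p), 0)
  expect_identical(msc_density("G2", p$tau0 + 0.01, p$tau0 + 0.005, p), 0)

  mass <- function(cls) {
    if (cls == "G1a") {
      integrate(function(t1) sapply(t1, function(tt1)
        integrate(function(t0) msc_density("G1a", tt1, t0, p),
                  p$tau0, Inf, rel.tol = 1e-10)$value),
        p$tau1, p$tau0, rel.tol = 1e-9)$value
    } else {
      integrate(function(t1) sapply(t1, function(tt1)
        integrate(function(t0) msc_density(cls, tt1, t0, p),
                  tt1, Inf, rel.tol = 1e-10)$value),
        p$tau0, Inf, rel.tol = 1e-9)$value
    }
  }
  m <- vapply(c("G1a", "G1b", "G2", "G3"), mass, numeric(1))
  expect_equal(unname(m), c(1 - p$phi, p$phi / 3, p$phi / 3, p$phi / 3),
               tolerance = 1e-8)
  expect_equal(sum(m), 1, tolerance = 1e-8)
})

test_that("conditional pattern probabilities match a base-enumeration oracle", {
  expect_equal(unname(pattern_probs(0, 0)[1, ]), c(1, 0, 0, 0, 0))
  expect_equal(unname(pattern_probs(Inf, Inf)[1, ]),
               c(1, 3, 3, 3, 6) / 16, tolerance = 1e-15)
  expect_error(pattern_probs(0.01, 0.02), class = "coaltrio_domain_error")

  withr::with_seed(42, {
    for (i in 1:100) {
      t1 <- runif(1, 0, 0.4)
      t0 <- t1 + runif(1, 0, 0.4)
      expect_equal(unname(pattern_probs(t0, t1)[1, ]),
                   enum_pattern_probs(t0, t1), tolerance = 1e-12)
    }
  })
})

test_that("pattern vectors are probability vectors and respect the class permutations", {
  withr::with_seed(7, {
    t1 <- runif(50, 0, 1)
    t0 <- t1 + runif(50, 0, 1)
    P <- pattern_probs(t0, t1)
    expect_true(all(P >= 0))
    expect_equal(rowSums(P), rep(1, 50), tolerance = 1e-12)
    expect_true(all(P[, 2] > P[, 3]))          # p1 > p2 when t0 > t1
    expect_equal(P[, 3], P[, 4])               # p2 = p3
  })
  p1a <- pattern_probs_class("G1a", 0.05, 0.02)
  expect_identical(p1a, pattern_probs_class("G1b", 0.05, 0.02))
  p2 <- pattern_probs_class("G2", 0.05, 0.02)
  expect_equal(p2[1, c(1, 3, 2, 4, 5)], p1a[1, ], ignore_attr = TRUE)
  p3 <- pattern_probs_class("G3", 0.05, 0.02)
  expect_equal(unname(p3[1, c(1, 4, 2, 3, 5)]), unname(p1a[1, c(1, 2, 3, 4, 5)]))
})

test_that("marginal pattern probabilities reproduce the reference values and the MC mixture", {
  mp <- marginal_pattern_probs(p_hard)
  expect_equal(unname(mp$pbar),
               c(0.92831926, 0.023777106, 0.023372801, 0.023372801,
                 0.001158033), tolerance = 1e-7)
  expect_equal(sum(mp$pbar), 1, tolerance = 1e-12)

  # no-divergence limit
  tiny <- marginal_pattern_probs(msc_params(2e-9, 1e-9, 1e-9, 1e-9))
  expect_equal(unname(tiny$pbar), c(1, 0, 0, 0, 0), tolerance = 1e-7)

  # Monte-Carlo mixture of per-class conditional probabilities
  gt <- sim_gene_trees(p_hard, m = 2e5, seed = 99)
  P <- coaltrio:::gene_tree_pattern_probs(gt$cls, gt$t0, gt$t1)
  se <- apply(P, 2, sd) / sqrt(nrow(P))
  expect_true(all(abs(colMeans(P) - mp$pbar) < 4 * se + 1e-12))

  # ordering and c0 = c1 = 0 under equal theta
  for (pp in random_params(25, seed = 3)) {
    m <- marginal_pattern_probs(pp)
    expect_true(m$pbar[2] > m$pbar[3])
    expect_equal(unname(m$pbar[3]), unname(m$pbar[4]))
    expect_true(all(m$pbar >= 0))
    expect_equal(sum(m$pbar), 1, tolerance = 1e-12)
  }
  meq <- marginal_pattern_probs(msc_params(0.02, 0.01, 0.03, 0.03))
  expect_equal(meq$c0, 0)
  expect_equal(meq$c1, 0)
})

test_that("the equal-theta marginal model agrees with an independent evaluation", {
  m1 <- marginal_pattern_probs_equal_theta(0.02, 0.01, 0.02)
  m2 <- marginal_pattern_probs(msc_params(0.02, 0.01, 0.02, 0.02))
  expect_equal(m1$pbar, m2$pbar, tolerance = 1e-14)

  # independently coded reduction
  a0 <- exp(-8 * 0.02 / 3) / (3 + 4 * 0.02)
  a1 <- exp(-8 * 0.01 / 3) / (3 + 4 * 0.02)
  b <- exp(-4 * 0.01 / 3) / (3 + 2 * 0.02)
  ref <- c((1 + 18 * a0 + 54 * a0 * b + 9 * a1) / 16,
           3 * (1 - 6 * a0 - 18 * a0 * b + 9 * a1) / 16,
           3 * (1 + 6 * a0 - 18 * a0 * b - 3 * a1) / 16,
           3 * (1 + 6 * a0 - 18 * a0 * b - 3 * a1) / 16,
           6 * (1 - 6 * a0 + 18 * a0 * b - 3 * a1) / 16)
  expect_equal(unname(m1$pbar), ref, tolerance = 1e-14)
})

test_that("parameters can be read from plain-text configuration", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("tau0 = 0.02", "tau1 = 0.019", "theta0 = 0.01",
               "theta1 = 0.05"), f)
  p <- read_msc_params(f)
  expect_equal(p$phi, exp(-0.04))
  f2 <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("tau0: 0.02", "tau1: 0.01", "theta0: 0.02", "theta1: 0.02",
               "label: S1"), f2)
  expect_equal(read_msc_params(f2)$tau1, 0.01)
  expect_equal(internal_branch_coalescent_units(p), 0.04)
})
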