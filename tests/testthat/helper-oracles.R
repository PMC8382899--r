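# Shared fixtures and independent oracles.

# The challenging species tree used throughout the numerical work.
p_hard <- msc_params(0.02, 0.019, 0.01, 0.05)
# The parameter set used for the concatenation-bias experiment.
p_bias <- msc_params(0.02, 0.01, 0.02, 0.01)

# Brute-force site-pattern probabilities for gene tree G1 = ((a,b),c) with
# node ages t1 (ab) and t0 (root), by enumerating ancestral and tip bases
# with JC transition probabilities. Independent of the closed form.
enum_pattern_probs <- function(t0, t1) {
  jc <- function(t) {
    same <- 1 / 4 + 3 / 4 * exp(-4 * t / 3)
    diff <- 1 / 4 - 1 / 4 * exp(-4 * t / 3)
    M <- matrix(diff, 4, 4)
    diag(M) <- same
    M
  }
  Mrc <- jc(t0)         # root -> c
  Mri <- jc(t0 - t1)    # root -> internal (ab ancestor)
  Mia <- jc(t1)         # internal -> a or b
  out <- numeric(5)
  for (r in 1:4) for (i in 1:4) for (a in 1:4) for (b in 1:4) for (cc in 1:4) {
    pr <- 0.25 * Mri[r, i] * Mia[i, a] * Mia[i, b] * Mrc[r, cc]
    cls <- if (a == b && b == cc) 1L
    else if (a == b) 2L
    else if (b == cc) 3L
    else if (cc == a) 4L
    else 5L
    out[cls] <- out[cls] + pr
  }
  out
}

# Adaptive nested integration of the per-locus MSC likelihood in time space;
# independent of the package's quadrature scheme.
loglik_oracle <- function(x, p, rel.tol = 1e-11) {
  gA <- function(t1s) sapply(t1s, function(tt1)
    integrate(function(t0) {
      pr <- pattern_probs(t0, rep(tt1, length(t0)))
      msc_density("G1a", tt1, t0, p) * exp(as.vector(log(pr) %*% x))
    }, p$tau0, Inf, rel.tol = rel.tol / 10, abs.tol = 0)$value)
  IA <- integrate(gA, p$tau1, p$tau0, rel.tol = rel.tol, abs.tol = 0)$value
  IB <- sum(sapply(c("G1b", "G2", "G3"), function(cl)
    integrate(function(t1s) sapply(t1s, function(tt1)
      integrate(function(t0) {
        pr <- pattern_probs_class(cl, t0, rep(tt1, length(t0)))
        msc_density(cl, tt1, t0, p) * exp(as.vector(log(pr) %*% x))
      }, tt1, Inf, rel.tol = rel.tol / 10, abs.tol = 0)$value),
      p$tau0, Inf, rel.tol = rel.tol, abs.tol = 0)$value))
  log(IA + IB)
}

# Random valid parameter draws for property tests.
random_params <- function(k, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(k), function(i) {
      tau1 <- runif(1, 0.002, 0.05)
      msc_params(tau1 + runif(1, 1e-4, 0.05), tau1,
                 runif(1, 0.002, 0.08), runif(1, 0.002, 0.08))
    })
  })
}
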