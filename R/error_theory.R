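# Normal-approximation theory for the species-tree estimation error: the
# probability that the sample mean of an exchangeable triple (z1, z2, z3)
# with mean (mu1, mu2, mu2), mu1 > mu2, fails to put z1 on top.

check_cov_triple <- function(dmu, sigma1_sq, sigma2_sq, sigma12, sigma23) {
  if (!is.finite(dmu) || dmu < 0)
    abort("dmu must be >= 0", class = "coaltrio_domain_error")
  if (sigma1_sq <= 0 || sigma2_sq <= 0)
    abort("variances must be positive", class = "coaltrio_domain_error")
  if (sigma2_sq < sigma23)
    abort("sigma2_sq - sigma23 must be nonnegative",
          class = "coaltrio_domain_error")
  S <- matrix(c(sigma1_sq, sigma12, sigma12,
                sigma12, sigma2_sq, sigma23,
                sigma12, sigma23, sigma2_sq), 3, 3)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    abort("implied 3x3 covariance is not positive semidefinite",
          class = "coaltrio_domain_error")
  invisible(S)
}

#' Normal approximation to the species-tree error probability
#'
#' For i.i.d. per-locus triples with means (mu1, mu2, mu2) and exchangeable
#' covariance (variance sigma1^2 for the first coordinate, sigma2^2 for the
#' other two, covariance sigma12 between the first and either other, sigma23
#' between the two others), approximates
#' zeta = P(zbar1 < max(zbar2, zbar3)) over m loci by
#' \deqn{\Phi\left(\frac{-\Delta\mu\sqrt{m} + \sqrt{(\sigma_2^2-\sigma_{23})/\pi}}
#'  {\sqrt{\sigma_1^2 - 2\sigma_{12} + \sigma_2^2 - (\sigma_2^2-\sigma_{23})/\pi}}\right).}
#'
#' @param m Number of loci (sample size).
#' @param dmu Mean difference mu1 - mu2 (>= 0).
#' @param sigma1_sq,sigma2_sq,sigma12,sigma23 Covariance structure of the
#'   exchangeable triple.
#' @return The approximate error probability.
#' @examples
#' # multinomial reduction: q1 = 0.3594737, q2 = 0.3202631, m = 1000
#' zeta_normal(1000, 0.0392106,
#'             0.3594737 * (1 - 0.3594737), 0.3202631 * (1 - 0.3202631),
#'             -0.3594737 * 0.3202631, -0.3202631^2)
#' @export
zeta_normal <- function(m, dmu, sigma1_sq, sigma2_sq, sigma12, sigma23) {
  dmu <- unname(dmu); sigma1_sq <- unname(sigma1_sq)
  sigma2_sq <- unname(sigma2_sq); sigma12 <- unname(sigma12)
  sigma23 <- unname(sigma23)
  check_cov_triple(dmu, sigma1_sq, sigma2_sq, sigma12, sigma23)
  if (m < 1) abort("m must be >= 1", class = "coaltrio_domain_error")
  half_range <- (sigma2_sq - sigma23) / pi
  den_sq <- sigma1_sq - 2 * sigma12 + sigma2_sq - half_range
  if (den_sq <= 0)
    abort("degenerate covariance: nonpositive denominator",
          class = "coaltrio_domain_error")
  pnorm((-dmu * sqrt(m) + sqrt(half_range)) / sqrt(den_sq))
}

#' Multinomial form of the error approximation
#'
#' The specialization of [zeta_normal()] when the per-locus triple is a
#' single multinomial trial with category probabilities (q1, q2, q2),
#' q1 > q2: sigma_jj = qj (1 - qj), sigma_jk = -qj qk, giving
#' \deqn{\zeta(m, q_1, q_2) = \Phi\left(\frac{-\Delta q\sqrt m + \sqrt{q_2/\pi}}
#'   {\sqrt{q_1 + q_2 - \Delta q^2 - q_2/\pi}}\right).}
#'
#' @param m Number of loci.
#' @param q1 Probability of the category matching the species tree.
#' @param q2 Probability of either mismatching category (0 < q2 < q1,
#'   q1 + 2 q2 <= 1).
#' @return The approximate error probability.
#' @examples
#' zeta_multinomial(1000, 0.3594737, 0.3202631)  # ~0.113
#' @export
zeta_multinomial <- function(m, q1, q2) {
  q1 <- unname(q1); q2 <- unname(q2)
  if (!(q2 > 0) || !(q1 > q2) || q1 + 2 * q2 > 1 + 1e-12)
    abort("require 0 < q2 < q1 and q1 + 2 q2 <= 1",
          class = "coaltrio_domain_error")
  dq <- q1 - q2
  pnorm((-dq * sqrt(m) + sqrt(q2 / pi)) /
          sqrt(q1 + q2 - dq^2 - q2 / pi))
}

#' Discontinuity-corrected multinomial error approximation (experimental)
#'
#' A variant of [zeta_multinomial()] that subtracts a discontinuity
#' correction 1/(q1 - q2) from the mean term and drops the correlation and
#' small-probability terms. The published rendering of this expression is
#' ambiguous and no parse we tried reproduces its reference values, so the
#' function is provided for completeness behind an `experimental` flag and is
#' never used as a default predictor; see the package vignette. The
#' correction is meaningless unless m >> 1/(q1 - q2); when the correction
#' term exceeds the main term the result is flagged inapplicable (`NA`).
#'
#' @inheritParams zeta_multinomial
#' @param experimental Must be set to `TRUE` to obtain a value.
#' @return The approximate error probability, or `NA` with attribute
#'   `inapplicable = TRUE` when m <= 1/(q1 - q2)^2.
#' @export
zeta_zly <- function(m, q1, q2, experimental = FALSE) {
  q1 <- unname(q1); q2 <- unname(q2)
  if (!experimental)
    abort(paste("zeta_zly is experimental (unresolved published form);",
                "pass experimental = TRUE to evaluate it"),
          class = "coaltrio_domain_error")
  if (!(q2 > 0) || !(q1 > q2) || q1 + 2 * q2 > 1 + 1e-12)
    abort("require 0 < q2 < q1 and q1 + 2 q2 <= 1",
          class = "coaltrio_domain_error")
  dq <- q1 - q2
  if (dq * m <= 1 / dq)
    return(structure(NA_real_, inapplicable = TRUE))
  pnorm((-dq * sqrt(m) - 1 / dq + sqrt(q2 / pi)) /
          sqrt(q1 + q2 - q2 / pi))
}

#' Lower and upper bounds on the species-tree error probability
#'
#' Computes the bound pair around [zeta_normal()]: with
#' s1^2 = sigma1^2 - 2 sigma12 + sigma2^2 - (sigma2^2 - sigma23)/2,
#' s2^2 = (sigma2^2 - sigma23)/2, a = s2/s1, b = dmu sqrt(m)/s1, and
#' h = b / sqrt(1 + a^2),
#' \deqn{\Phi(-h)\,(1 + (2/\pi)\arctan a) \le \zeta < 2\,\Phi(-h),}
#' with equality in the lower bound at h = b = 0.
#'
#' @inheritParams zeta_normal
#' @return A list of class `zeta_bounds` with `s1_sq`, `s2_sq`, `a`, `b`,
#'   `h`, `lower` (zetaL1) and `upper` (zetaU1).
#' @export
zeta_bounds <- function(m, dmu, sigma1_sq, sigma2_sq, sigma12, sigma23) {
  dmu <- unname(dmu); sigma1_sq <- unname(sigma1_sq)
  sigma2_sq <- unname(sigma2_sq); sigma12 <- unname(sigma12)
  sigma23 <- unname(sigma23)
  check_cov_triple(dmu, sigma1_sq, sigma2_sq, sigma12, sigma23)
  s2_sq <- (sigma2_sq - sigma23) / 2
  s1_sq <- sigma1_sq - 2 * sigma12 + sigma2_sq - s2_sq
  if (s1_sq <= 0)
    abort("degenerate covariance: s1^2 <= 0", class = "coaltrio_domain_error")
  a <- sqrt(s2_sq / s1_sq)
  b <- dmu * sqrt(m) / sqrt(s1_sq)
  h <- b / sqrt(1 + a^2)
  structure(list(s1_sq = s1_sq, s2_sq = s2_sq, a = a, b = b, h = h,
                 lower = pnorm(-h) * (1 + 2 / pi * atan(a)),
                 upper = 2 * pnorm(-h)),
            class = "zeta_bounds")
}

#' @export
print.zeta_bounds <- function(x, ...) {
  cat(sprintf("zeta bounds: [%.4f, %.4f]  (a = %.6g, b = %.6g, h = %.6g)\n",
              x$lower, x$upper, x$a, x$b, x$h))
  invisible(x)
}

# Multinomial covariance inputs (sigma1_sq, sigma2_sq, sigma12, sigma23) for
# trinomial category probabilities (q1, q2, q2).
multinomial_cov <- function(q1, q2) {
  q1 <- unname(q1); q2 <- unname(q2)
  list(sigma1_sq = q1 * (1 - q1), sigma2_sq = q2 * (1 - q2),
       sigma12 = -q1 * q2, sigma23 = -q2^2)
}

#' Single-site covariance of the informative pattern frequencies
#'
#' The multinomial(1) covariance of the informative-pattern frequencies
#' (f1, f2, f3) at one site: sigma_jj = pbar_j (1 - pbar_j),
#' sigma_jk = -pbar_j pbar_k.
#'
#' @param pbar Marginal 5-vector (e.g. `marginal_pattern_probs(p)$pbar`) or a
#'   `marginal_pattern_model`.
#' @return A symmetric 3 x 3 covariance matrix (patterns `xxy`, `yxx`,
#'   `xyx`).
#' @export
sigma_one_site <- function(pbar) {
  if (inherits(pbar, "marginal_pattern_model")) pbar <- pbar$pbar
  q <- pbar[2:4]
  S <- -outer(q, q)
  diag(S) <- q * (1 - q)
  S
}

#' Among-locus covariance of the pattern probabilities (infinite sites)
#'
#' At n = infinity the per-locus frequencies equal the per-locus pattern
#' probabilities (p_i1, p_i2, p_i3), whose distribution over loci is the
#' 4-component mixture induced by the gene-tree classes and coalescent times.
#' This covariance has no convenient closed form and is estimated by Monte
#' Carlo over simulated gene trees.
#'
#' @inheritParams noncoalescence_prob
#' @param R Number of simulated gene trees (>= 1e4).
#' @param seed Integer seed.
#' @return 3 x 3 covariance matrix with attributes `R`, `mean` (Monte Carlo
#'   mean of the triple), and `mc_se` (standard errors of the means).
#' @export
sigma_infinite <- function(params, R = 1e6, seed = 1L) {
  p <- as_msc_params(params)
  if (R < 1e4) abort("R must be >= 1e4", class = "coaltrio_domain_error")
  # accumulate cross-products blockwise to bound memory
  acc <- local({
    sum1 <- numeric(3); sumsq <- matrix(0, 3, 3); n <- 0
    list(add = function(M) {
      sum1 <<- sum1 + colSums(M)
      sumsq <<- sumsq + crossprod(M)
      n <<- n + nrow(M)
    }, get = function() list(sum1 = sum1, sumsq = sumsq, n = n))
  })
  stream_blocks(seed, R, function(B, k) {
    gt <- sim_gene_tree_block(B, p)
    P <- gene_tree_pattern_probs(gt$cls, gt$t0, gt$t1)[, 2:4, drop = FALSE]
    acc$add(P)
    numeric(0)
  })
  st <- acc$get()
  # stream_blocks generates whole blocks; n may exceed R, harmless for moments
  mu <- st$sum1 / st$n
  S <- st$sumsq / st$n - outer(mu, mu)
  S <- S * st$n / (st$n - 1)
  dimnames(S) <- list(pattern_names()[2:4], pattern_names()[2:4])
  structure(S, R = st$n, mean = setNames(mu, pattern_names()[2:4]),
            mc_se = sqrt(pmax(diag(S), 0) / st$n))
}

#' Mixed-n covariance of per-locus pattern frequencies
#'
#' For loci of n sites the covariance of the per-locus informative-pattern
#' frequencies decomposes into within-locus multinomial noise and among-locus
#' coalescent variation:
#' Sigma(n) = (1/n) Sigma(1) + ((n-1)/n) Sigma(infinity), elementwise.
#'
#' @param sigma1 3 x 3 covariance at n = 1 ([sigma_one_site()]).
#' @param sigma_inf 3 x 3 covariance at n = infinity ([sigma_infinite()]).
#' @param n Sites per locus (>= 1; `Inf` allowed).
#' @return 3 x 3 covariance matrix.
#' @export
sigma_mixed <- function(sigma1, sigma_inf, n) {
  if (n < 1) abort("n must be >= 1", class = "coaltrio_domain_error")
  if (is.infinite(n)) return(sigma_inf[1:3, 1:3])
  (1 / n) * sigma1[1:3, 1:3] + ((n - 1) / n) * sigma_inf[1:3, 1:3]
}

# Collapse a (nearly) exchangeable 3x3 covariance of (f1, f2, f3) into the
# four scalars used by zeta_normal, symmetrizing Monte Carlo noise.
exchangeable_cov <- function(S) {
  list(sigma1_sq = S[1, 1],
       sigma2_sq = (S[2, 2] + S[3, 3]) / 2,
       sigma12 = (S[1, 2] + S[1, 3]) / 2,
       sigma23 = S[2, 3])
}

#' Probabilities of the estimated gene tree at sequence length n
#'
#' Computes (g1, g2, g3), the probabilities that the ML gene tree estimated
#' from one locus of n sites is G1, G2, G3, together with the probability of
#' an unresolved (tied) estimate. At n = 1 these are exact (g1 = pbar1,
#' g2 = g3 = pbar2, tie mass pbar0 + pbar4); at n = infinity the estimated
#' tree is the true tree (g = the gene-tree topology probabilities, no ties);
#' at finite n > 1 they are estimated by Monte Carlo with strict-argmax wins.
#' Phylogenetic error makes g1 < P(G1) at any finite n.
#'
#' @inheritParams noncoalescence_prob
#' @param n Sites per locus (1, finite > 1, or `Inf`).
#' @param R Monte Carlo replicates for finite n > 1.
#' @param seed Integer seed.
#' @return A list of class `gene_tree_recovery`: `g1`, `g2`, `g3`, `p_tie`,
#'   `mode` (`"exact-n1"`, `"exact-inf"` or `"monte-carlo"`), and for Monte
#'   Carlo also `R`, `seed`, `mc_se`.
#' @examples
#' gene_tree_recovery(msc_params(0.02, 0.019, 0.01, 0.05), n = 1)
#' @export
gene_tree_recovery <- function(params, n, R = 1e5, seed = 1L) {
  p <- as_msc_params(params)
  if (is.infinite(n)) {
    g <- gene_tree_topology_probs(p)
    return(structure(list(g1 = unname(g[1]), g2 = unname(g[2]),
                          g3 = unname(g[3]), p_tie = 0, mode = "exact-inf"),
                     class = "gene_tree_recovery"))
  }
  if (n < 1) abort("n must be >= 1", class = "coaltrio_domain_error")
  if (n == 1) {
    pb <- marginal_pattern_probs(p)$pbar
    return(structure(list(g1 = unname(pb[2]), g2 = unname(pb[3]),
                          g3 = unname(pb[4]),
                          p_tie = unname(pb[1] + pb[5]), mode = "exact-n1"),
                     class = "gene_tree_recovery"))
  }
  wins <- stream_blocks(seed, R, function(B, k) {
    gt <- sim_gene_tree_block(B, p)
    P <- gene_tree_pattern_probs(gt$cls, gt$t0, gt$t1)
    X <- rmultinom_rows(n, P)
    Y <- X[, 2:4, drop = FALSE]
    mx <- pmax(Y[, 1], Y[, 2], Y[, 3])
    strict <- (Y == mx) & (rowSums(Y == mx) == 1)
    cbind(strict, tie = rowSums(Y == mx) > 1)
  })
  g <- colMeans(wins)
  structure(list(g1 = unname(g[1]), g2 = unname(g[2]), g3 = unname(g[3]),
                 p_tie = unname(g[4]), mode = "monte-carlo", R = R,
                 seed = as.integer(seed),
                 mc_se = sqrt(g * (1 - g) / R)),
            class = "gene_tree_recovery")
}

#' @export
print.gene_tree_recovery <- function(x, ...) {
  cat(sprintf("Estimated-gene-tree probabilities (%s): g1 = %.5f, g2 = %.5f, g3 = %.5f, P(tie) = %.5f\n",
              x$mode, x$g1, x$g2, x$g3, x$p_tie))
  invisible(x)
}

new_error_prediction <- function(method, m, n, value, flavor, extra = list()) {
  structure(c(list(method = method, m = m, n = n, value = value,
                   flavor = flavor), extra),
            class = "error_prediction")
}

#' @export
print.error_prediction <- function(x, ...) {
  cat(sprintf("Predicted species-tree error (%s, %s): %.6g  [m = %g, n = %s]\n",
              x$method, x$flavor, x$value, x$m,
              if (is.infinite(x$n)) "Inf" else format(x$n)))
  invisible(x)
}

#' @method tidy error_prediction
#' @export
tidy.error_prediction <- function(x, ...) {
  tibble::tibble(method = x$method, flavor = x$flavor, m = x$m, n = x$n,
                 error = x$value)
}

#' Predicted two-step species-tree error
#'
#' Applies [zeta_multinomial()] with the estimated-gene-tree probabilities of
#' [gene_tree_recovery()]: error ~ zeta(m, g1(n), g2(n)).
#'
#' @inheritParams gene_tree_recovery
#' @param m Number of loci.
#' @return An `error_prediction` (flavor `"zeta"`) carrying the recovery
#'   probabilities in `$recovery`.
#' @export
predict_two_step_error <- function(params, m, n, R = 1e5, seed = 1L) {
  rec <- gene_tree_recovery(params, n, R = R, seed = seed)
  # ties split evenly contribute equally to all trees and do not move the
  # argmax; renormalization over resolved loci cancels in the comparison
  val <- zeta_multinomial(m, rec$g1, (rec$g2 + rec$g3) / 2)
  new_error_prediction("two_step", m, n, val, "zeta",
                       extra = list(recovery = rec))
}

#' Predicted isml / concatenation species-tree error
#'
#' Applies [zeta_normal()] with mean difference pbar1 - pbar2 and the
#' mixed-n covariance Sigma(n) of the per-locus informative-pattern
#' frequencies: error ~ zetaN(m, pbar1 - pbar2, Sigma(n)). With
#' `correlations = FALSE` the cross covariances sigma12 and sigma23 are set
#' to 0 (the "no correlation" variant, less accurate at large n).
#'
#' @inheritParams gene_tree_recovery
#' @param m Number of loci.
#' @param R Monte Carlo gene trees for the n = infinity covariance component.
#' @param correlations Keep the cross covariances (default `TRUE`).
#' @return An `error_prediction` (flavor `"zetaN"` or `"zetaN0"`).
#' @export
predict_isml_error <- function(params, m, n, R = 1e6, seed = 1L,
                               correlations = TRUE) {
  p <- as_msc_params(params)
  pb <- marginal_pattern_probs(p)$pbar
  dmu <- unname(pb[2] - pb[3])
  S1 <- sigma_one_site(pb)
  S <- if (n == 1) S1
       else sigma_mixed(S1, sigma_infinite(p, R = R, seed = seed), n)
  cv <- exchangeable_cov(S)
  if (!correlations) {
    cv$sigma12 <- 0
    cv$sigma23 <- 0
  }
  val <- zeta_normal(m, dmu, cv$sigma1_sq, cv$sigma2_sq, cv$sigma12,
                     cv$sigma23)
  new_error_prediction("isml", m, n, val,
                       if (correlations) "zetaN" else "zetaN0",
                       extra = list(cov = cv, dmu = dmu))
}

#' Exact ML species-tree error in the infinite-sites limit
#'
#' With infinitely long sequences the gene tree and its coalescent times are
#' known at every locus and the ML species tree follows the smallest pairwise
#' coalescent time. The species tree is wrong only if the ingroup pair fails
#' to coalesce in its ancestral population at every locus and the first
#' root-population coalescence at the decisive locus is one of the two wrong
#' pairs: error = phi^m * 2/3, exact for every m >= 0.
#'
#' @inheritParams noncoalescence_prob
#' @param m Number of loci (>= 0).
#' @return An `error_prediction` (flavor `"exact-inf"`).
#' @examples
#' ml_error_infinite_n(msc_params(0.02, 0.019, 0.01, 0.05), m = 10)  # ~0.45
#' @export
ml_error_infinite_n <- function(params, m) {
  p <- as_msc_params(params)
  if (m < 0) abort("m must be >= 0", class = "coaltrio_domain_error")
  new_error_prediction("ml", m, Inf, p$phi^m * 2 / 3, "exact-inf")
}

#' Kullback-Leibler prediction of the full-ML species-tree error
#'
#' Research-grade predictor of the error of the full-likelihood method at
#' finite n: the per-locus log-likelihoods (l1, l2, l3) evaluated at the true
#' parameters (tree S1) and at the pseudotrue parameters of the misspecified
#' trees S2, S3 form the exchangeable triple of [zeta_normal()], with mean
#' difference equal to the Kullback-Leibler divergence D12 from S2 to S1.
#' Pseudotrue parameters are found by maximizing the average log-likelihood
#' over a large simulated reference sample, and the moments of (l1, l2, l3)
#' are then estimated on a fresh Monte Carlo sample.
#'
#' @inheritParams noncoalescence_prob
#' @param n Sites per locus (n >= 2 recommended; the model is not fully
#'   identifiable at n = 1).
#' @param m Number of loci for the predicted error.
#' @param R_ref Loci in the simulated reference sample for the pseudotrue
#'   search and moment estimation.
#' @param seed Integer seed.
#' @param quad_nodes Quadrature nodes for the likelihood evaluations.
#' @return An `error_prediction` (flavor `"kl-mc"`) with a `kl` element
#'   holding D12, D13, the per-locus moments, and the pseudotrue parameter
#'   sets.
#' @export
kl_predict_ml_error <- function(params, n, m, R_ref = 2e3, seed = 1L,
                                quad_nodes = 16L) {
  p <- as_msc_params(params)
  ref <- sim_dataset(p, m = R_ref, n = n, seed = seed)
  X <- counts_matrix(ref)
  per_locus_ll <- function(tree, pr) {
    q <- msc_quadrature(pr, quad_nodes)
    Xp <- X[, tree_count_perm(tree), drop = FALSE]
    row_logsumexp(Xp %*% t(q$logP), q$logw)
  }
  fit2 <- ml_msc_fit(X, tree = 2, quad_nodes = quad_nodes)
  fit3 <- ml_msc_fit(X, tree = 3, quad_nodes = quad_nodes)
  l1 <- per_locus_ll(1, p)
  l2 <- per_locus_ll(2, fit2$params_hat)
  l3 <- per_locus_ll(3, fit3$params_hat)
  L <- cbind(l1, l2, l3)
  mu <- colMeans(L)
  S <- stats::cov(L)
  D12 <- mu[1] - mu[2]
  D13 <- mu[1] - mu[3]
  cv <- exchangeable_cov(S)
  val <- zeta_normal(m, max(unname(mu[1] - (mu[2] + mu[3]) / 2), 0),
                     cv$sigma1_sq, cv$sigma2_sq, cv$sigma12, cv$sigma23)
  new_error_prediction("ml", m, n, val, "kl-mc",
    extra = list(kl = list(D12 = unname(D12), D13 = unname(D13), mu = mu,
                           Sigma_l = S,
                           pseudotrue = list(S2 = fit2$params_hat,
                                             S3 = fit3$params_hat),
                           R_ref = R_ref, seed = as.integer(seed))))
}
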