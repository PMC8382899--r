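#' Site-pattern probabilities given a gene tree with known node ages
#'
#' Under the Jukes-Cantor model with a molecular clock, the alignment column
#' for three sequences falls into one of five pattern classes, in the fixed
#' order used throughout this package: `xxx`, `xxy`, `yxx`, `xyx`, `xyz`
#' (x, y, z any three distinct nucleotides). Given gene tree G1 = ((a,b),c)
#' with node ages `t1` (a-b coalescence) and `t0` (root), the probabilities
#' are polynomial in u = exp(-8 t0 / 3) and v = exp(-4 t1 / 3):
#' \deqn{p_0 = (1 + 3v^2 + 6u + 6uv)/16,\quad
#'       p_1 = (3 + 9v^2 - 6u - 6uv)/16,}
#' \deqn{p_2 = p_3 = (3 - 3v^2 + 6u - 6uv)/16,\quad
#'       p_4 = (6 - 6v^2 - 12u + 12uv)/16.}
#' Infinite times are accepted as a sentinel meaning u = v = 0 (random
#' sequences).
#'
#' @param t0 Root node age(s), substitutions/site; `t0 >= t1`.
#' @param t1 Ingroup node age(s), substitutions/site; `t1 >= 0`. Recycled
#'   against `t0`.
#' @return A numeric matrix with one row per (t0, t1) pair and columns
#'   `xxx`, `xxy`, `yxx`, `xyx`, `xyz`; rows sum to 1.
#' @examples
#' pattern_probs(0.03, 0.02)
#' pattern_probs(Inf, Inf)  # 1/16, 3/16, 3/16, 3/16, 6/16
#' @export
pattern_probs <- function(t0, t1) {
  n <- max(length(t0), length(t1))
  t0 <- rep_len(t0, n); t1 <- rep_len(t1, n)
  if (any(t1 < 0) || any(t0 < t1))
    abort("require 0 <= t1 <= t0", class = "coaltrio_domain_error")
  pattern_probs_uv(exp(-8 * t0 / 3), exp(-4 * t1 / 3))
}

# Eq.-3 pattern probabilities directly from u = exp(-8 t0/3), v = exp(-4 t1/3)
# (no ordering check; used by the quadrature machinery).
pattern_probs_uv <- function(u, v) {
  p <- cbind(1 + 3 * v^2 + 6 * u + 6 * u * v,
             3 + 9 * v^2 - 6 * u - 6 * u * v,
             3 - 3 * v^2 + 6 * u - 6 * u * v,
             3 - 3 * v^2 + 6 * u - 6 * u * v,
             6 - 6 * v^2 - 12 * u + 12 * u * v) / 16
  colnames(p) <- pattern_names()
  p
}

pattern_names <- function() c("xxx", "xxy", "yxx", "xyx", "xyz")

# Column permutations mapping the G1-topology probability vector
# (p0, p1, p2, p2, p4) onto the other topologies:
#   G2 = ((b,c),a): (p0, p2, p1, p2, p4);  G3 = ((c,a),b): (p0, p2, p2, p1, p4)
class_perm <- function(cls) {
  switch(as.character(cls),
         G1a = , G1b = , G1 = , `1` = 1:5,
         G2 = , `2` = c(1L, 3L, 2L, 4L, 5L),
         G3 = , `3` = c(1L, 3L, 4L, 2L, 5L),
         abort("unknown gene-tree class", class = "coaltrio_domain_error"))
}

#' Site-pattern probabilities for a given gene-tree class
#'
#' As [pattern_probs()] but permuted for the topology of the gene-tree class:
#' classes `G1a` and `G1b` share topology G1 and give identical probabilities;
#' `G2` swaps the roles of patterns `xxy` and `yxx`; `G3` swaps `xxy` and
#' `xyx`.
#'
#' @param cls Gene-tree class: `"G1a"`, `"G1b"`, `"G2"`, `"G3"` (topology
#'   indices 1-3 also accepted).
#' @inheritParams pattern_probs
#' @return Numeric matrix as in [pattern_probs()].
#' @export
pattern_probs_class <- function(cls, t0, t1) {
  p <- pattern_probs(t0, t1)
  p[, class_perm(cls), drop = FALSE]
}

#' Joint density of gene-tree class and coalescent times under the MSC
#'
#' Density f(class, t1, t0 | S1, params) for the four gene-tree classes of the
#' rooted triplet: class `G1a` (a and b coalesce in their ancestral population,
#' tau1 < t1 < tau0 < t0) has density
#' (2/theta1) exp(-2 (t1 - tau1)/theta1) * (2/theta0) exp(-2 (t0 - tau0)/theta0);
#' each of `G1b`, `G2`, `G3` (all three lineages enter the root population,
#' tau0 < t1 < t0) has density
#' phi * (2/theta0)^2 exp(-6 (t1 - tau0)/theta0 - 2 (t0 - t1)/theta0).
#' Outside the class's support the density is 0. The class masses are
#' (1 - phi, phi/3, phi/3, phi/3).
#'
#' @param cls Gene-tree class: `"G1a"`, `"G1b"`, `"G2"` or `"G3"`.
#' @param t1,t0 Coalescent times (node ages), substitutions/site; vectors are
#'   recycled.
#' @inheritParams noncoalescence_prob
#' @return Nonnegative density value(s).
#' @export
msc_density <- function(cls, t1, t0, params) {
  p <- as_msc_params(params)
  cls <- as.character(cls)
  if (!all(cls %in% c("G1a", "G1b", "G2", "G3")))
    abort("class must be one of G1a, G1b, G2, G3",
          class = "coaltrio_domain_error")
  n <- max(length(cls), length(t1), length(t0))
  cls <- rep_len(cls, n); t1 <- rep_len(t1, n); t0 <- rep_len(t0, n)
  out <- numeric(n)
  a <- cls == "G1a"
  ok <- a & t1 > p$tau1 & t1 < p$tau0 & t0 > p$tau0
  out[ok] <- (2 / p$theta1) * exp(-2 * (t1[ok] - p$tau1) / p$theta1) *
    (2 / p$theta0) * exp(-2 * (t0[ok] - p$tau0) / p$theta0)
  ok <- !a & t1 > p$tau0 & t0 > t1
  out[ok] <- p$phi * (2 / p$theta0)^2 *
    exp(-6 * (t1[ok] - p$tau0) / p$theta0 - 2 * (t0[ok] - t1[ok]) / p$theta0)
  out
}

#' Marginal site-pattern probabilities under the MSC
#'
#' Averages the conditional pattern probabilities of [pattern_probs_class()]
#' over the MSC distribution of gene trees and coalescent times, giving the
#' marginal probabilities pbar of the five site patterns for a site drawn at a
#' random locus. These are the closed forms used by the independent-sites ML
#' method; with intermediates
#' a0 = exp(-8 tau0/3)/(3 + 4 theta0), a1 = exp(-8 tau1/3)/(3 + 4 theta1),
#' b = exp(-4 tau1/3)/(3 + 2 theta1),
#' c0 = 2 phi (theta1 - theta0) exp(-4 tau0/3) / ((3 + 2 theta0)(3 + 2 theta1)),
#' c1 = 4 phi (theta1 - theta0) a0 / (3 + 4 theta1):
#' \deqn{\bar p_0 = (1 + 18 a_0 + 54 a_0 b + 54 a_0 c_0 + 9 c_1 + 9 a_1)/16,}
#' \deqn{\bar p_1 = 3(1 - 6 a_0 - 18 a_0 b - 18 a_0 c_0 + 9 c_1 + 9 a_1)/16,}
#' \deqn{\bar p_2 = \bar p_3
#'   = 3(1 + 6 a_0 - 18 a_0 b - 18 a_0 c_0 - 3 c_1 - 3 a_1)/16,}
#' \deqn{\bar p_4 = 6(1 - 6 a_0 + 18 a_0 b + 18 a_0 c_0 - 3 c_1 - 3 a_1)/16.}
#' Always pbar1 > pbar2 = pbar3 when `tau0 > tau1`, and c0 = c1 = 0 when
#' `theta0 == theta1`.
#'
#' @inheritParams noncoalescence_prob
#' @return A list of class `marginal_pattern_model` with elements `pbar`
#'   (named 5-vector), the intermediates `a0`, `a1`, `b`, `c0`, `c1`, and
#'   `params`.
#' @examples
#' marginal_pattern_probs(msc_params(0.02, 0.019, 0.01, 0.05))$pbar
#' @export
marginal_pattern_probs <- function(params) {
  p <- as_msc_params(params)
  a0 <- exp(-8 * p$tau0 / 3) / (3 + 4 * p$theta0)
  a1 <- exp(-8 * p$tau1 / 3) / (3 + 4 * p$theta1)
  b  <- exp(-4 * p$tau1 / 3) / (3 + 2 * p$theta1)
  c0 <- 2 * p$phi * (p$theta1 - p$theta0) * exp(-4 * p$tau0 / 3) /
    ((3 + 2 * p$theta0) * (3 + 2 * p$theta1))
  c1 <- 4 * p$phi * (p$theta1 - p$theta0) * a0 / (3 + 4 * p$theta1)
  pbar <- c(
    (1 + 18 * a0 + 54 * a0 * b + 54 * a0 * c0 + 9 * c1 + 9 * a1) / 16,
    3 * (1 - 6 * a0 - 18 * a0 * b - 18 * a0 * c0 + 9 * c1 + 9 * a1) / 16,
    3 * (1 + 6 * a0 - 18 * a0 * b - 18 * a0 * c0 - 3 * c1 - 3 * a1) / 16,
    3 * (1 + 6 * a0 - 18 * a0 * b - 18 * a0 * c0 - 3 * c1 - 3 * a1) / 16,
    6 * (1 - 6 * a0 + 18 * a0 * b + 18 * a0 * c0 - 3 * c1 - 3 * a1) / 16)
  names(pbar) <- pattern_names()
  structure(list(pbar = pbar, a0 = a0, a1 = a1, b = b, c0 = c0, c1 = c1,
                 params = p),
            class = "marginal_pattern_model")
}

#' @export
print.marginal_pattern_model <- function(x, ...) {
  cat("Marginal site-pattern probabilities under the MSC:\n")
  print(signif(x$pbar, 8))
  invisible(x)
}

#' Marginal site-pattern probabilities assuming equal population sizes
#'
#' The reduction of [marginal_pattern_probs()] under theta0 = theta1 = theta,
#' in which the cross terms c0 and c1 vanish. This three-parameter model
#' (tau0, tau1, theta) is the one inverted by [isml_estimate_params()].
#'
#' @param tau0,tau1 Divergence ages, substitutions/site, 0 < tau1 < tau0.
#' @param theta Shared population-size parameter, > 0.
#' @return A `marginal_pattern_model` as in [marginal_pattern_probs()].
#' @export
marginal_pattern_probs_equal_theta <- function(tau0, tau1, theta) {
  marginal_pattern_probs(msc_params(tau0, tau1, theta, theta))
}
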