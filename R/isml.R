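# Independent-sites ML parameter estimation under theta0 = theta1.

#' Independent-sites ML parameter estimates from pooled frequencies
#'
#' Inverts the equal-theta marginal pattern model
#' ([marginal_pattern_probs_equal_theta()]) at the observed pooled site-pattern
#' frequencies. With moments
#' h1 = f0 + f1, h2 = f0 + (f2 + f3)/2, h3 = f1 + (f2 + f3)/2 and
#' A = 4 h3 - 2 h1 - 1, B = 4 h1 - 1, C = 4 h2 - 1, the shared theta solves
#' the quadratic 4 A^2 theta^2 + (3 A^2 - B C^2)(4 theta + 3) = 0, which has a
#' unique positive root whenever B C^2 > 3 A^2; tau1 and tau0 then follow by
#' inverting a1 = B/9 and a0 = C/9 at theta-hat. If the generating process has
#' theta0 != theta1 the estimates are finite but inconsistent (the species
#' tree itself is still consistently estimated).
#'
#' @param freqs Pooled site-pattern frequencies (5-vector summing to 1), or a
#'   dataset/counts object which is pooled and normalized first.
#' @return A list of class `isml_fit` with `theta_hat`, `tau0_hat`,
#'   `tau1_hat`, and the moments `h1`, `h2`, `h3`, `A`, `B`, `C`.
#' @examples
#' pb <- marginal_pattern_probs_equal_theta(0.02, 0.01, 0.02)$pbar
#' isml_estimate_params(pb)  # exact recovery
#' @export
isml_estimate_params <- function(freqs) {
  f <- as.numeric(counts_matrix(freqs)[1L, ])
  if (any(f < 0) || sum(f) <= 0)
    abort("invalid frequencies", class = "coaltrio_domain_error")
  f <- f / sum(f)
  h1 <- f[1] + f[2]
  h2 <- f[1] + (f[3] + f[4]) / 2
  h3 <- f[2] + (f[3] + f[4]) / 2
  A <- 4 * h3 - 2 * h1 - 1
  B <- 4 * h1 - 1
  C <- 4 * h2 - 1
  fail <- function(cond) abort(
    paste0("isml moment inversion failed: ", cond),
    class = "coaltrio_estimation_error")
  if (B <= 0) fail("B = 4 h1 - 1 <= 0 (saturation: a1 <= 0)")
  if (C <= 0) fail("C = 4 h2 - 1 <= 0 (saturation: a0 <= 0)")
  if (A == 0) fail("A = 4 h3 - 2 h1 - 1 = 0")
  D <- B * C^2 - 3 * A^2
  if (D <= 0) fail("B C^2 <= 3 A^2 (no positive root for theta)")
  theta <- (D + sqrt(D^2 + 3 * A^2 * D)) / (2 * A^2)
  tau1 <- -3 / 8 * log(B * (3 + 4 * theta) / 9)
  tau0 <- -3 / 8 * log(C * (3 + 4 * theta) / 9)
  if (!(tau1 > 0) || !(tau0 > tau1))
    fail(sprintf("inverted ages violate 0 < tau1 < tau0 (%.4g, %.4g)",
                 tau1, tau0))
  structure(list(theta_hat = theta, tau0_hat = tau0, tau1_hat = tau1,
                 h1 = h1, h2 = h2, h3 = h3, A = A, B = B, C = C),
            class = "isml_fit")
}

#' @export
print.isml_fit <- function(x, ...) {
  cat(sprintf("isml parameter estimates (theta0 = theta1 assumed):\n  theta_hat = %.6g, tau0_hat = %.6g, tau1_hat = %.6g\n",
              x$theta_hat, x$tau0_hat, x$tau1_hat))
  invisible(x)
}

#' @method tidy isml_fit
#' @export
tidy.isml_fit <- function(x, ...) {
  tibble::tibble(term = c("theta", "tau0", "tau1"),
                 estimate = c(x$theta_hat, x$tau0_hat, x$tau1_hat))
}
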