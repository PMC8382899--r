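# Replicated-simulation experiment drivers and diagnostics.

# Even-tie error credit for a matrix of support statistics (datasets x 3):
# a dataset scores 0 if tree 1 is the strict argmax, 1 - 1/|tie| if tree 1
# ties for the maximum, and 1 otherwise.
error_credit <- function(Y, tol = 0) {
  mx <- pmax(Y[, 1], Y[, 2], Y[, 3])
  isw <- Y >= mx - tol
  k <- rowSums(isw)
  1 - isw[, 1] / k
}

#' Monte Carlo species-tree error rate of an estimation method
#'
#' Simulates `R` independent datasets of `m` loci with `n` sites each under
#' the MSC + JC model and scores the fraction on which the method fails to
#' recover the true species tree S1, with dataset-level ties credited evenly
#' (a tie among k trees including S1 counts (k-1)/k of an error).
#'
#' The infinite-sites regime (`n = Inf`) is scored per method with the exact
#' constructions: two-step uses the true gene-tree topologies; isml /
#' concatenation averages the exact per-locus pattern probabilities; ML
#' applies the minimum-coalescent-time rule. At `n = 1` all four methods
#' reduce exactly to the pooled-pattern argmax, and are scored by that shared
#' rule; at finite n > 1 the full ML method fits all three trees by
#' [ml_msc_species_tree()] per replicate (slow; a runtime advisory is issued
#' for large R).
#'
#' @inheritParams noncoalescence_prob
#' @param method One of `"two_step"`, `"isml"`, `"concat"`, `"ml"` (isml and
#'   concat share the pooled-count rule and give identical results).
#' @param m Loci per dataset.
#' @param n Sites per locus (1, finite > 1, or `Inf`).
#' @param R Number of replicate datasets.
#' @param seed Integer seed.
#' @param tie_policy Locus-level tie policy for two-step (see [two_step()]).
#' @param quad_nodes,n_starts Settings forwarded to [ml_msc_species_tree()]
#'   for the finite-n ML method.
#' @return A one-row tibble: `method`, `m`, `n`, `R`, `error`, `mc_se`
#'   (binomial standard error), `seed`, `tie_policy`.
#' @export
run_error_experiment <- function(params, method = c("two_step", "isml",
                                                    "concat", "ml"),
                                 m, n, R, seed = 1L, tie_policy = "even",
                                 quad_nodes = 16L, n_starts = 2L) {
  p <- as_msc_params(params)
  method <- match.arg(method)
  if (m < 1 || R < 1) abort("m and R must be >= 1",
                            class = "coaltrio_domain_error")
  credits <-
    if (is.infinite(n)) error_experiment_inf(p, method, m, R, seed)
    else if (method == "ml" && n > 1)
      error_experiment_ml(p, m, n, R, seed, quad_nodes, n_starts)
    else error_experiment_counts(p, method, m, n, R, seed, tie_policy)
  err <- mean(credits)
  tibble::tibble(method = method, m = m, n = n, R = R, error = err,
                 mc_se = sqrt(err * (1 - err) / R), seed = as.integer(seed),
                 tie_policy = tie_policy)
}

# Summary methods (and n = 1 generally) on simulated count data, chunked over
# replicate datasets. All count-based methods consume the RNG identically, so
# the same seed yields the same simulated datasets for every method.
error_experiment_counts <- function(p, method, m, n, R, seed, tie_policy) {
  # n = 1: the pooled informative counts are sufficient for every method
  # (even locus ties add the same credit to all three tallies, and dropping
  # tied loci removes zeros), and are exactly multinomial with the marginal
  # pattern probabilities -- so replicate datasets can be drawn directly.
  if (n == 1 && !(method == "two_step" && tie_policy == "random")) {
    pb <- marginal_pattern_probs(p)$pbar
    return(with_rng(seed, {
      tallies <- t(rmultinom(R, m, pb))[, 2:4, drop = FALSE]
      error_credit(tallies)
    }))
  }
  chunk <- max(1L, min(R, floor(2e5 / m)))
  with_rng(seed, {
    credits <- numeric(0)
    done <- 0L
    while (done < R) {
      r <- min(chunk, R - done)
      gt <- sim_gene_tree_block(r * m, p)
      P <- gene_tree_pattern_probs(gt$cls, gt$t0, gt$t1)
      X <- rmultinom_rows(n, P)
      id <- rep(seq_len(r), each = m)
      Y <- if (method == "two_step") {
        rowsum(locus_votes(X, tie_policy), id)
      } else {
        rowsum(X[, 2:4, drop = FALSE], id)
      }
      credits <- c(credits, error_credit(Y, tol = 1e-9))
      done <- done + r
    }
    credits
  })
}

# Infinite-sites constructions, per method.
error_experiment_inf <- function(p, method, m, R, seed) {
  if (method == "two_step") {
    g <- gene_tree_topology_probs(p)
    return(with_rng(seed, {
      tallies <- t(rmultinom(R, m, g))
      error_credit(tallies)
    }))
  }
  chunk <- max(1L, min(R, floor(2e5 / m)))
  with_rng(seed, {
    credits <- numeric(0)
    done <- 0L
    while (done < R) {
      r <- min(chunk, R - done)
      gt <- sim_gene_tree_block(r * m, p)
      id <- rep(seq_len(r), each = m)
      if (method == "ml") {
        # species tree of the locus with the smallest first coalescent time
        ord <- order(id, gt$t1)
        first <- ord[!duplicated(id[ord])]
        top <- topology_index(gt$cls)[first]
        credits <- c(credits, as.numeric(top != 1L))
      } else {
        P <- gene_tree_pattern_probs(gt$cls, gt$t0, gt$t1)
        Y <- rowsum(P[, 2:4, drop = FALSE], id)
        credits <- c(credits, error_credit(Y))
      }
      done <- done + r
    }
    credits
  })
}

# Full ML at finite n > 1: per-replicate three-tree fits.
error_experiment_ml <- function(p, m, n, R, seed, quad_nodes, n_starts) {
  if (R * m > 5e5)
    rlang::inform(paste("full-ML error experiment with", R, "replicates of",
                        m, "loci: expect a long runtime"))
  vapply(seq_len(R), function(r) {
    d <- sim_dataset(p, m = m, n = n, seed = seed + r - 1L)
    call <- suppressWarnings(
      ml_msc_species_tree(d, quad_nodes = quad_nodes, n_starts = n_starts))
    k <- length(call$tie)
    1 - (1L %in% call$tie) / k
  }, numeric(1))
}

#' Exact species-tree error by enumeration (single-site loci, small m)
#'
#' For n = 1 the pooled informative counts are multinomial with the marginal
#' pattern probabilities, so for small m the exact error of the shared
#' pooled-pattern rule can be computed by complete enumeration of count
#' outcomes, with even tie credit. Used as a brute-force oracle for the
#' simulation machinery and (loosely) the normal approximations.
#'
#' @inheritParams noncoalescence_prob
#' @param m Number of loci (kept small; the outcome space grows as m^4).
#' @return The exact error probability.
#' @export
exact_error_n1 <- function(params, m) {
  pb <- marginal_pattern_probs(as_msc_params(params))$pbar
  err <- 0
  for (x1 in 0:m) for (x2 in 0:(m - x1)) for (x3 in 0:(m - x1 - x2))
    for (x4 in 0:(m - x1 - x2 - x3)) {
      x0 <- m - x1 - x2 - x3 - x4
      pr <- dmultinom(c(x0, x1, x2, x3, x4), prob = pb)
      mx <- max(x1, x2, x3)
      tie <- c(x1, x2, x3) == mx
      err <- err + pr * (1 - tie[1] / sum(tie))
    }
  err
}

#' Probit-linearity diagnostic for error-rate sweeps
#'
#' The theory predicts that the probit transform of the species-tree error,
#' qnorm(error), decreases linearly in sqrt(m). This fits that line by least
#' squares over a sweep of error estimates.
#'
#' @param estimates A tibble with columns `m` and `error` (e.g. rows from
#'   [run_error_experiment()] or tidied [predict_two_step_error()] values).
#' @return An object of class `probit_fit` with `slope`, `intercept`,
#'   `r_squared`, the filtered `data`, and the underlying `lm` fit.
#' @export
probit_linearity <- function(estimates) {
  df <- tibble::as_tibble(estimates)
  bad <- df$error <= 0 | df$error >= 1 | !is.finite(df$error)
  if (any(bad)) {
    warn(sprintf("excluding %d point(s) with error outside (0, 1)",
                 sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) < 3)
    abort("need at least 3 usable points", class = "coaltrio_domain_error")
  df$probit <- qnorm(df$error)
  df$sqrt_m <- sqrt(df$m)
  fit <- lm(probit ~ sqrt_m, data = df)
  # direct R^2 (summary.lm warns when the fit is numerically perfect)
  ss_tot <- sum((df$probit - mean(df$probit))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 data = df, model = fit),
            class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("Probit-linearity fit: qnorm(e) = %.5g %+.5g sqrt(m), R^2 = %.5f\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' @method glance probit_fit
#' @export
glance.probit_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared, n_points = nrow(x$data))
}

#' Analytic summary-method error table over sequence lengths
#'
#' Rebuilds the theory grid for the two summary methods at a fixed number of
#' loci: for each n it reports the estimated-gene-tree probabilities and tie
#' mass ([gene_tree_recovery()]), the two-step zeta prediction and
#' Theorem-1(b) bound quantities, and the isml zetaN / zetaN0 predictions
#' with bounds from the mixed covariance Sigma(n). Optionally adds simulated
#' error rates for both methods.
#'
#' @inheritParams noncoalescence_prob
#' @param m Number of loci (default 1000).
#' @param n_values Sequence lengths (default `c(1, 2, 10, 100, 1000, Inf)`).
#' @param R_recovery Monte Carlo loci for finite-n gene-tree recovery.
#' @param R_cov Monte Carlo gene trees for the n = infinity covariance.
#' @param R_sim Replicates for simulated error columns (`NULL` to skip).
#' @param seed Integer seed.
#' @return A tibble with one row per n; deterministic given `seed`.
#' @export
table1_report <- function(params, m = 1000, n_values = c(1, 2, 10, 100, 1000,
                                                         Inf),
                          R_recovery = 1e5, R_cov = 1e6, R_sim = NULL,
                          seed = 1L) {
  p <- as_msc_params(params)
  pb <- marginal_pattern_probs(p)$pbar
  S1 <- sigma_one_site(pb)
  SInf <- sigma_infinite(p, R = R_cov, seed = seed)
  dmu <- unname(pb[2] - pb[3])
  rows <- purrr::map(n_values, function(n) {
    rec <- gene_tree_recovery(p, n, R = R_recovery, seed = seed + 1L)
    g1 <- rec$g1; g2 <- (rec$g2 + rec$g3) / 2
    cv2 <- multinomial_cov(g1, g2)
    b2 <- zeta_bounds(m, g1 - g2, cv2$sigma1_sq, cv2$sigma2_sq, cv2$sigma12,
                      cv2$sigma23)
    Sn <- sigma_mixed(S1, SInf, n)
    cvi <- exchangeable_cov(Sn)
    bi <- zeta_bounds(m, dmu, cvi$sigma1_sq, cvi$sigma2_sq, cvi$sigma12,
                      cvi$sigma23)
    out <- tibble::tibble(
      n = n, m = m, p_tie = rec$p_tie, g1 = g1, g2 = g2,
      zeta_2step = zeta_multinomial(m, g1, g2),
      a_2step = b2$a, b_2step = b2$b,
      lower_2step = b2$lower, upper_2step = b2$upper,
      zetaN_isml = zeta_normal(m, dmu, cvi$sigma1_sq, cvi$sigma2_sq,
                               cvi$sigma12, cvi$sigma23),
      zetaN0_isml = zeta_normal(m, dmu, cvi$sigma1_sq, cvi$sigma2_sq, 0, 0),
      a_isml = bi$a, b_isml = bi$b,
      lower_isml = bi$lower, upper_isml = bi$upper)
    if (!is.null(R_sim)) {
      out$e_2step <- run_error_experiment(p, "two_step", m, n, R_sim,
                                          seed = seed + 2L)$error
      out$e_isml <- run_error_experiment(p, "isml", m, n, R_sim,
                                         seed = seed + 3L)$error
    }
    out
  })
  dplyr::bind_rows(rows)
}
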