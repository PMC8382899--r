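# Full maximum likelihood under the MSC: per-locus likelihoods computed by
# summing over the four gene-tree classes and integrating over coalescent
# times with fixed Gaussian (Jacobi-weight) quadrature on mutation-scale
# coordinates.

# Count-column permutations that turn the likelihood for species tree S2/S3
# into the S1 form applied to relabelled data (species relabelling permutes
# the informative site patterns).
tree_count_perm <- function(tree) {
  switch(tree, 1:5, c(1L, 3L, 4L, 2L, 5L), c(1L, 4L, 2L, 3L, 5L))
}

# Gauss-Jacobi rule for the probability density r exp(-r s) on s in (0, Inf)
# after the mutation-scale substitution xi = exp(-a s): the integral becomes
# (r/a) * Int_0^1 xi^(r/a - 1) g(xi) d xi, a polynomial-in-xi integrand
# against a Jacobi weight. Nodes/weights come from the Golub-Welsch
# eigenvalue method for the Jacobi recurrence; weights are normalized to sum
# to 1, so Sum w_i g(xi_i) approximates E[g(exp(-a s))]. The site-pattern
# probabilities are polynomials in xi, so the rule is exact for pattern-count
# exponents up to (2K - 1) per axis.
gauss_jacobi_expmap <- function(K, rate, a) {
  be <- rate / a - 1            # Jacobi weight xi^be on [0, 1]
  if (be <= -1)
    abort("invalid Jacobi exponent", class = "coaltrio_numeric_error")
  d <- numeric(K)
  d[1] <- be / (be + 2)
  if (K > 1) {
    kk <- seq_len(K - 1)
    d[-1] <- be^2 / ((2 * kk + be) * (2 * kk + be + 2))
  }
  e <- numeric(max(K - 1, 0))
  if (K > 1) {
    e[1] <- sqrt(4 * (1 + be) / ((2 + be)^2 * (3 + be)))
    if (K > 2) {
      kk <- 2:(K - 1)
      e[-1] <- sqrt(4 * kk^2 * (kk + be)^2 /
                      ((2 * kk + be)^2 * (2 * kk + be + 1) * (2 * kk + be - 1)))
    }
  }
  Tm <- diag(d, K, K)
  if (K > 1) {
    Tm[cbind(seq_len(K - 1), 2:K)] <- e
    Tm[cbind(2:K, seq_len(K - 1))] <- e
  }
  es <- eigen(Tm, symmetric = TRUE)
  x <- (es$values + 1) / 2
  w <- es$vectors[1, ]^2
  ord <- order(x)
  list(x = x[ord], w = (w / sum(w))[ord])
}

# Composite Gauss-Legendre rule for the truncated-exponential t1 axis of
# class G1a, in the probability coordinate y = exp(-2 (t1 - tau1) / theta1)
# on (phi, 1): panels graded geometrically toward 0 keep the mildly singular
# factor v = v(tau1) y^(2 theta1 / 3) well resolved for any phi. Weights sum
# to 1 - phi (the class mass).
region_a_t1_rule <- function(phi, Kp) {
  brk <- 1
  b <- 0.25
  while (b > phi && length(brk) < 28) {
    brk <- c(brk, b)
    b <- b / 4
  }
  brk <- rev(c(brk, phi))
  x <- numeric(0); w <- numeric(0)
  for (i in seq_len(length(brk) - 1)) {
    gl <- pracma::gaussLegendre(Kp, brk[i], brk[i + 1])
    x <- c(x, gl$x); w <- c(w, gl$w)
  }
  list(x = x, w = w)
}

# Quadrature representation of the per-locus MSC likelihood: log pattern
# probabilities (N x 5) and log weights (length N), such that
# log f(x) = logsumexp_i (logw_i + sum_j x_j logP[i, j]).
#
# Region A (class G1a: t1 in (tau1, tau0), t0 in (tau0, Inf)): composite
# Gauss-Legendre on the probability-transformed t1 axis crossed with the
# Jacobi rule for the half-infinite t0 axis (u = u(tau0) eta linear in the
# transformed coordinate). Region B (classes G1b/G2/G3: t1 in (tau0, Inf),
# t0 = t1 + s; mass phi/3 per class): Jacobi rules on both axes, with
# u = u(tau0) xi^2 eta and v = v(tau0) xi polynomial in the coordinates.
# All pattern probabilities are nonnegative on both regions (t0 >= t1
# implies u <= v^2) and the weights sum to 1 exactly.
msc_quadrature <- function(params, K) {
  p <- params
  Kp <- max(8L, K %/% 2L)
  rA <- region_a_t1_rule(p$phi, Kp)                     # A: y axis
  r_t0 <- gauss_jacobi_expmap(K, 2 / p$theta0, 8 / 3)   # A: t0 - tau0; B: s
  r_b1 <- gauss_jacobi_expmap(K, 6 / p$theta0, 4 / 3)   # B: t1 - tau0
  u00 <- exp(-8 * p$tau0 / 3)
  v0 <- exp(-4 * p$tau0 / 3)
  nA <- length(rA$x)
  t1A <- p$tau1 - (p$theta1 / 2) * log(rA$x)
  vA <- exp(-4 * t1A / 3)
  PA <- pattern_probs_uv(rep(u00 * r_t0$x, each = nA), rep(vA, times = K))
  wA <- as.vector(outer(rA$w, r_t0$w))
  xiB <- rep(r_b1$x, times = K)
  etaB <- rep(r_t0$x, each = K)
  PB <- pattern_probs_uv(u00 * xiB^2 * etaB, v0 * xiB)
  wB <- as.vector(outer(r_b1$w, r_t0$w)) * (p$phi / 3)
  logP <- log(pmax(rbind(PA,
                         PB,
                         PB[, c(1L, 3L, 2L, 4L, 5L), drop = FALSE],
                         PB[, c(1L, 3L, 4L, 2L, 5L), drop = FALSE]),
                   1e-300))
  list(logP = logP, logw = log(c(wA, wB, wB, wB)))
}

#' MSC log-likelihood of a multilocus dataset for one species tree
#'
#' Computes the log-likelihood of per-locus site-pattern counts under the MSC
#' + JC model: for each locus the probability is the mixture over the four
#' gene-tree classes of the multinomial kernel (pattern probabilities raised
#' to the counts; the multinomial coefficient, constant across species trees
#' and parameters, is omitted), with coalescent times integrated out by
#' fixed Gaussian (Jacobi-weight) quadrature on mutation-scale coordinates,
#' under which the pattern probabilities are polynomial in the transformed
#' variables and the rule is exact for per-axis count exponents up to
#' 2 `quad_nodes` - 1. Species
#' trees S2 and S3 are handled by the corresponding relabelling of the count
#' categories.
#'
#' @param data Dataset tibble, count matrix, or 5-vector (one locus).
#' @param tree Species-tree index 1, 2, or 3.
#' @inheritParams noncoalescence_prob
#' @param quad_nodes Quadrature nodes per dimension (K >= 8; default 32).
#' @param weights Optional per-row multiplicities (rows of `data` then need
#'   not be unique); mainly used internally by the optimizer.
#' @return The log-likelihood (0 for an empty dataset).
#' @examples
#' p <- msc_params(0.02, 0.019, 0.01, 0.05)
#' msc_loglik(c(0, 1, 0, 0, 0), tree = 1, params = p)  # log pbar_1
#' @export
msc_loglik <- function(data, tree = 1L, params, quad_nodes = 32L,
                       weights = NULL) {
  p <- as_msc_params(params)
  if (quad_nodes < 8) abort("quad_nodes must be >= 8",
                            class = "coaltrio_domain_error")
  X <- counts_matrix(data)
  if (nrow(X) == 0) return(0)
  if (is.null(weights)) {
    cc <- collapse_counts(X)
    X <- cc$X
    weights <- cc$w
  }
  X <- X[, tree_count_perm(tree), drop = FALSE]
  q <- msc_quadrature(p, quad_nodes)
  tlogP <- t(q$logP)
  wq <- exp(q$logw)
  N <- length(wq)
  chunk <- max(1L, floor(4e6 / N))
  ll <- 0
  for (i0 in seq(1L, nrow(X), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, nrow(X))
    S <- X[idx, , drop = FALSE] %*% tlogP
    mx <- S[cbind(seq_along(idx), max.col(S, ties.method = "first"))]
    ll <- ll + sum(weights[idx] * (mx + log(as.vector(exp(S - mx) %*% wq))))
  }
  if (!is.finite(ll))
    abort("non-finite MSC log-likelihood (quadrature failure)",
          class = "coaltrio_numeric_error")
  ll
}

# Collapse duplicate count rows into unique rows with multiplicities.
collapse_counts <- function(X) {
  key <- X[, 1] + 0
  n1 <- max(rowSums(X)) + 1
  for (j in 2:5) key <- key * n1 + X[, j]
  tab <- tapply(rep(1, nrow(X)), key, sum)
  list(X = X[match(as.numeric(names(tab)), key), , drop = FALSE],
       w = as.numeric(tab))
}

#' Maximize the MSC likelihood for one species tree
#'
#' Maximizes [msc_loglik()] over (tau0, tau1, theta0, theta1) with
#' 0 < tau1 < tau0, using bounded quasi-Newton optimization on the
#' log-transformed coordinates (log tau1, log(tau0 - tau1), log theta0,
#' log theta1) and multiple starts (a heuristic start from the pooled
#' frequencies via [isml_estimate_params()] plus dispersed variants).
#' Parameters are bounded below at 1e-8; estimates on that bound are flagged
#' as boundary solutions.
#'
#' @inheritParams msc_loglik
#' @param n_starts Number of optimization starts (>= 1).
#' @param hessian If `TRUE`, also return a variance matrix for the natural
#'   parameters from the numerically differentiated observed information.
#' @return An object of class `msc_fit`: `params_hat` ([msc_params()]),
#'   `loglik`, `tree`, `quad_nodes`, `convergence` (0 = converged),
#'   `boundary` flag, optionally `vcov`, and the per-start diagnostics.
#' @export
ml_msc_fit <- function(data, tree = 1L, params = NULL, quad_nodes = 32L,
                       n_starts = 3L, hessian = FALSE) {
  X <- counts_matrix(data)
  cc <- if (nrow(X) > 1) collapse_counts(X) else list(X = X, w = rep(1, nrow(X)))
  nll <- function(par) {
    e <- exp(par)
    pr <- msc_params(e[1] + e[2], e[1], e[3], e[4])
    -msc_loglik(cc$X, tree = tree, params = pr, quad_nodes = quad_nodes,
                weights = cc$w)
  }
  start_nat <- ml_start_heuristic(X, tree)
  starts <- list(log(start_nat))
  if (n_starts >= 2) starts <- c(starts, list(log(start_nat * 3)))
  if (n_starts >= 3) starts <- c(starts, list(log(start_nat / 3)))
  lb <- rep(log(1e-8), 4)
  ub <- rep(log(2), 4)
  best <- NULL
  diags <- list()
  for (s in starts) {
    s <- pmin(pmax(s, lb + 0.1), ub - 0.1)
    fit <- tryCatch(
      optim(s, nll, method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(maxit = 500, factr = 4.5e7)),
      error = function(e) NULL)
    if (is.null(fit)) next
    diags[[length(diags) + 1L]] <- fit[c("value", "convergence")]
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    abort("MSC optimization failed from all starts",
          class = "coaltrio_numeric_error")
  e <- exp(best$par)
  params_hat <- msc_params(e[1] + e[2], e[1], e[3], e[4])
  boundary <- any(best$par <= lb + 1e-6)
  out <- list(params_hat = params_hat, loglik = -best$value, tree = tree,
              quad_nodes = quad_nodes, convergence = best$convergence,
              boundary = boundary, starts = diags)
  if (hessian) {
    H <- stats::optimHess(best$par, nll)
    J <- rbind(tau0 = c(e[1], e[2], 0, 0),
               tau1 = c(e[1], 0, 0, 0),
               theta0 = c(0, 0, e[3], 0),
               theta1 = c(0, 0, 0, e[4]))
    V <- tryCatch(J %*% solve(H) %*% t(J), error = function(e) NULL)
    if (!is.null(V)) dimnames(V) <- list(rownames(J), rownames(J))
    out$vcov <- V
  }
  structure(out, class = "msc_fit")
}

# Heuristic natural-scale start (tau1, tau0 - tau1, theta0, theta1) from the
# pooled frequencies: the isml equal-theta inversion when admissible, else a
# distance-based fallback.
ml_start_heuristic <- function(X, tree) {
  pooled <- colSums(X[, tree_count_perm(tree), drop = FALSE])
  est <- tryCatch(isml_estimate_params(pooled), error = function(e) NULL)
  if (!is.null(est) && est$tau0_hat < 1 && est$theta_hat < 1)
    return(c(est$tau1_hat, est$tau0_hat - est$tau1_hat,
             est$theta_hat, est$theta_hat))
  f <- pooled / sum(pooled)
  d <- max(1 - f[1], 0.05)  # crude overall divergence scale
  tau1 <- d / 4
  c(tau1, tau1, d / 4, d / 4)
}

#' @export
print.msc_fit <- function(x, ...) {
  cat(sprintf("MSC ML fit for species tree S%d (loglik %.4f%s):\n", x$tree,
              x$loglik, if (x$boundary) ", boundary" else ""))
  p <- x$params_hat
  cat(sprintf("  tau0 = %.6g, tau1 = %.6g, theta0 = %.6g, theta1 = %.6g\n",
              p$tau0, p$tau1, p$theta0, p$theta1))
  invisible(x)
}

#' @method tidy msc_fit
#' @export
tidy.msc_fit <- function(x, ...) {
  est <- with(x$params_hat, c(tau0, tau1, theta0, theta1))
  out <- tibble::tibble(term = c("tau0", "tau1", "theta0", "theta1"),
                        estimate = est)
  if (!is.null(x$vcov))
    out$std.error <- sqrt(pmax(diag(x$vcov), 0))
  out
}

#' @method glance msc_fit
#' @export
glance.msc_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, tree = paste0("S", x$tree),
                 convergence = x$convergence, boundary = x$boundary)
}

#' Full-likelihood (MSC) species-tree estimate
#'
#' Fits the MSC model to the multilocus data for each of the three species
#' trees with [ml_msc_fit()] and selects the tree with the highest maximized
#' log-likelihood. Trees within `tie_tol` log-likelihood units of the maximum
#' are reported as a tie set. With one site per locus only three free pattern
#' frequencies are available for four parameters, so an identifiability
#' warning is emitted (the topology call remains valid).
#'
#' @inheritParams ml_msc_fit
#' @param tie_tol Log-likelihood tie tolerance (default 1e-6).
#' @return A `species_tree_call` (support = the three maximized
#'   log-likelihoods) with the per-tree `msc_fit`s in `$fits`.
#' @export
ml_msc_species_tree <- function(data, quad_nodes = 32L, n_starts = 3L,
                                tie_tol = 1e-6) {
  X <- counts_matrix(data)
  if (nrow(X) >= 1 && max(rowSums(X)) == 1)
    warn(paste("n = 1: the four MSC parameters are not identifiable from",
               "single-site loci"), class = "coaltrio_identifiability_warning")
  fits <- lapply(1:3, function(tr)
    ml_msc_fit(X, tree = tr, quad_nodes = quad_nodes, n_starts = n_starts))
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  call <- argmax_call(ll, tol = tie_tol)
  new_species_tree_call(call$winner, call$tie, ll, method = "ml",
                        extra = list(fits = fits))
}
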