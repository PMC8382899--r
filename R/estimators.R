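# Summary species-tree estimators: per-locus ML gene trees, two-step
# majority vote, and the pooled-count rule shared by concatenation and
# independent-sites ML.

new_species_tree_call <- function(winner, tie, support, method, extra = list()) {
  structure(c(list(winner = winner, tie = tie,
                   support = setNames(support, c("S1", "S2", "S3")),
                   method = method), extra),
            class = "species_tree_call")
}

#' @export
print.species_tree_call <- function(x, ...) {
  lab <- if (length(x$tie) > 1)
    paste0("tie {", paste0("S", x$tie, collapse = ", "), "}")
  else paste0("S", x$winner)
  cat(sprintf("Species-tree call (%s): %s\n", x$method, lab))
  cat("support:", paste(sprintf("%s = %.6g", names(x$support), x$support),
                        collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy species_tree_call
#' @export
tidy.species_tree_call <- function(x, ...) {
  tibble::tibble(tree = c("S1", "S2", "S3"),
                 support = unname(x$support),
                 winner = seq_len(3) %in% x$tie)
}

# argmax over the three informative categories with exact tie detection
# (tol > 0 for real-valued support such as log-likelihoods).
argmax_call <- function(s, tol = 0) {
  mx <- max(s)
  tie <- unname(which(s >= mx - tol))
  list(winner = tie[1], tie = tie)
}

#' ML gene tree from one locus's site-pattern counts
#'
#' Under JC and the clock, the maximum-likelihood gene tree for a locus is
#' determined by the counts of the three informative patterns: tree G_j wins
#' if its supporting count (`xxy` for G1, `yxx` for G2, `xyx` for G3) is the
#' strict maximum. Equal maxima are reported as a tie set.
#'
#' @param counts 5-vector of site-pattern counts (order `xxx`, `xxy`, `yxx`,
#'   `xyx`, `xyz`) or one-row dataset tibble.
#' @return A list with `winner` (smallest index among the maximal trees) and
#'   `tie` (integer vector of all maximal trees).
#' @examples
#' ml_gene_tree(c(0, 5, 3, 2, 0))  # G1
#' ml_gene_tree(c(0, 4, 4, 1, 1))  # tie {G1, G2}
#' @export
ml_gene_tree <- function(counts) {
  x <- counts_matrix(counts)[1L, ]
  argmax_call(x[2:4])
}

# Per-locus vote matrix (m x 3) for a dataset under a tie policy.
locus_votes <- function(X, tie_policy = c("even", "drop", "random")) {
  tie_policy <- match.arg(tie_policy)
  Y <- X[, 2:4, drop = FALSE]
  mx <- pmax(Y[, 1], Y[, 2], Y[, 3])
  W <- (Y == mx) * 1
  k <- rowSums(W)
  if (tie_policy == "even") {
    W <- W / k
  } else if (tie_policy == "drop") {
    W[k > 1, ] <- 0
  } else {
    tied <- which(k > 1)
    for (i in tied) {
      j <- sample(which(W[i, ] > 0), 1L)
      W[i, ] <- 0
      W[i, j] <- 1
    }
  }
  W
}

#' Two-step (majority-vote) species-tree estimate
#'
#' Estimates the ML gene tree at every locus ([ml_gene_tree()]) and uses the
#' most common topology as the species-tree estimate. Loci whose gene tree is
#' tied contribute according to `tie_policy`: `"even"` splits the locus vote
#' equally among the tied trees (the default), `"drop"` discards the locus,
#' `"random"` assigns it to one tied tree at random (seed-dependent).
#'
#' @param data Dataset tibble or m x 5 count matrix.
#' @param tie_policy Locus-level tie policy, see above.
#' @return A `species_tree_call` with support `(m1, m2, m3)` (possibly
#'   fractional under `"even"`).
#' @examples
#' d <- sim_dataset(msc_params(0.02, 0.019, 0.01, 0.05), m = 100, n = 10)
#' two_step(d)
#' @export
two_step <- function(data, tie_policy = c("even", "drop", "random")) {
  X <- counts_matrix(data)
  W <- locus_votes(X, tie_policy)
  mvec <- colSums(W)
  call <- argmax_call(mvec)
  new_species_tree_call(call$winner, call$tie, mvec,
                        method = "two_step")
}

#' Concatenation / independent-sites ML species-tree topology
#'
#' Both concatenation and independent-sites ML (isml) choose the species tree
#' whose supporting informative pattern has the largest pooled count across
#' loci: S_j wins if the pooled count of its pattern (`xxy` for S1, `yxx` for
#' S2, `xyx` for S3) is the strict maximum; equal maxima are a tie.
#'
#' @inheritParams two_step
#' @return A `species_tree_call` with the pooled informative counts as
#'   support.
#' @export
concat_isml_topology <- function(data) {
  pooled <- pooled_counts(data)
  call <- argmax_call(pooled[2:4])
  new_species_tree_call(call$winner, call$tie, unname(pooled[2:4]),
                        method = "concat_isml")
}

#' Species tree from true gene trees (infinite-sites maximum likelihood)
#'
#' In the infinite-sites limit the gene tree and its coalescent times are
#' observed without error at every locus, and the MSC likelihood is maximized
#' (to a singularity) by the species tree whose cherry matches the globally
#' smallest pairwise coalescent time: tree S1 if min t_ab over loci is the
#' smallest of the three pairwise minima, and so on. Since any locus that
#' coalesces before the root (class `G1a`) has t_ab < tau0 < t_bc, t_ca, the
#' winner is the topology of the locus with the smallest first coalescent
#' time.
#'
#' @param gene_trees A tibble from [sim_gene_trees()] (columns `topology`,
#'   `t1`, `t0`).
#' @return A `species_tree_call` with support = minus the minimum pairwise
#'   coalescent times (so that the winner maximizes support).
#' @export
species_tree_from_true_gene_trees <- function(gene_trees) {
  top <- gene_trees$topology
  t1 <- gene_trees$t1
  t0 <- gene_trees$t0
  if (length(top) < 1)
    abort("need at least one locus", class = "coaltrio_domain_error")
  mins <- vapply(1:3, function(j) {
    suppressWarnings(min(ifelse(top == j, t1, t0)))
  }, numeric(1))
  call <- argmax_call(-mins)
  new_species_tree_call(call$winner, call$tie, -mins, method = "ml_inf")
}
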