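# Exact simulator of gene trees, site-pattern counts, and alignments under
# the MSC + JC model for a species triplet.

# One block of gene trees, vectorized, with a fixed RNG consumption pattern
# (so block content depends only on the block's substream). Classes are coded
# G1a/G1b/G2/G3; topology(G1a) = topology(G1b) = G1.
sim_gene_tree_block <- function(B, params) {
  p <- params
  s1 <- rexp(B, rate = 2 / p$theta1)           # a-b waiting time in pop AB
  pick <- sample.int(3L, B, replace = TRUE)    # first pair in the root pop
  s1r <- rexp(B, rate = 6 / p$theta0)          # first coalescence, 3 lineages
  s0 <- rexp(B, rate = 2 / p$theta0)           # final coalescence, 2 lineages
  g1a <- p$tau1 + s1 < p$tau0
  cls <- ifelse(g1a, "G1a", c("G1b", "G2", "G3")[pick])
  t1 <- ifelse(g1a, p$tau1 + s1, p$tau0 + s1r)
  t0 <- ifelse(g1a, p$tau0, t1) + s0
  data.frame(cls = cls, t1 = t1, t0 = t0)
}

#' Simulate gene trees with coalescent times under the MSC
#'
#' Draws independent gene trees (class and node ages) for a species triplet:
#' an exponential waiting time s1 with mean theta1/2 is generated for the two
#' ingroup lineages; if tau1 + s1 < tau0 the class is `G1a` with
#' t1 = tau1 + s1 and t0 = tau0 + s0 (s0 exponential, mean theta0/2);
#' otherwise all three lineages enter the root population, the class is drawn
#' uniformly from `G1b`, `G2`, `G3`, and t1 = tau0 + s1' (s1' exponential,
#' mean theta0/6), t0 = t1 + s0.
#'
#' @inheritParams noncoalescence_prob
#' @param m Number of gene trees (loci) to draw.
#' @param seed Integer seed. Loci are generated on deterministic per-block
#'   substreams, so enlarging `m` extends the sample without changing earlier
#'   loci.
#' @return A tibble with columns `locus`, `cls`, `topology` (1, 2 or 3),
#'   `t1`, `t0`.
#' @examples
#' sim_gene_trees(msc_params(0.02, 0.019, 0.01, 0.05), m = 5, seed = 1)
#' @export
sim_gene_trees <- function(params, m, seed = 1L) {
  p <- as_msc_params(params)
  if (m < 1) abort("m must be >= 1", class = "coaltrio_domain_error")
  df <- stream_blocks(seed, m, function(B, k) sim_gene_tree_block(B, p))
  tibble::tibble(
    locus = seq_len(m),
    cls = df$cls,
    topology = topology_index(df$cls),
    t1 = df$t1,
    t0 = df$t0)
}

topology_index <- function(cls) {
  unname(c(G1a = 1L, G1b = 1L, G2 = 2L, G3 = 3L)[cls])
}

# Site-pattern probability matrix (m x 5) for simulated gene trees,
# permuted per class topology.
gene_tree_pattern_probs <- function(cls, t0, t1) {
  P <- pattern_probs(t0, t1)
  top <- topology_index(cls)
  i2 <- top == 2L; i3 <- top == 3L
  if (any(i2)) P[i2, ] <- P[i2, c(1L, 3L, 2L, 4L, 5L), drop = FALSE]
  if (any(i3)) P[i3, ] <- P[i3, c(1L, 3L, 4L, 2L, 5L), drop = FALSE]
  P
}

#' Simulate a multilocus site-pattern dataset under the MSC + JC model
#'
#' For each of `m` loci a gene tree with coalescent times is drawn as in
#' [sim_gene_trees()], its site-pattern probabilities are computed, and the
#' `n` sites of the locus are drawn multinomially. With `n = Inf` the locus is
#' represented by its exact per-locus pattern probabilities (the
#' infinite-sites regime) instead of counts.
#'
#' @inheritParams sim_gene_trees
#' @param n Sites per locus (>= 1), or `Inf` for the infinite-sites regime.
#' @return A tibble of class `msc_dataset` with columns `locus` and either
#'   integer counts `xxx`, `xxy`, `yxx`, `xyx`, `xyz` (finite `n`) or exact
#'   pattern frequencies in the same columns (`n = Inf`). Attributes `n`,
#'   `params`, and `seed` record provenance.
#' @examples
#' d <- sim_dataset(msc_params(0.02, 0.019, 0.01, 0.05), m = 4, n = 10, seed = 7)
#' pooled_counts(d)
#' @export
sim_dataset <- function(params, m, n, seed = 1L) {
  p <- as_msc_params(params)
  if (length(m) != 1 || is.na(m) || m < 1)
    abort("m must be >= 1", class = "coaltrio_domain_error")
  if (length(n) != 1 || is.na(n) || n < 1)
    abort("n must be >= 1 (or Inf)", class = "coaltrio_domain_error")
  X <- stream_blocks(seed, m, function(B, k) {
    gt <- sim_gene_tree_block(B, p)
    P <- gene_tree_pattern_probs(gt$cls, gt$t0, gt$t1)
    if (is.infinite(n)) P else rmultinom_rows(n, P)
  })
  out <- tibble::as_tibble(as.data.frame(X))
  names(out) <- pattern_names()
  out <- dplyr::bind_cols(tibble::tibble(locus = seq_len(m)), out)
  structure(out, n = n, params = p, seed = as.integer(seed),
            class = c("msc_dataset", class(out)))
}

#' Pool site-pattern counts across loci
#'
#' @param data A dataset tibble with pattern-count columns `xxx` .. `xyz`
#'   (e.g. from [sim_dataset()]).
#' @return Named numeric 5-vector of pooled counts (or pooled frequencies
#'   summing to `m` in the infinite-sites representation).
#' @export
pooled_counts <- function(data) {
  X <- counts_matrix(data)
  colSums(X)
}

# Extract the m x 5 pattern-count matrix from a dataset tibble, a matrix, or
# a bare 5-vector.
counts_matrix <- function(data) {
  if (is.matrix(data)) {
    X <- data
  } else if (is.data.frame(data)) {
    nm <- pattern_names()
    if (!all(nm %in% names(data)))
      abort("data must have columns xxx, xxy, yxx, xyx, xyz",
            class = "coaltrio_domain_error")
    X <- as.matrix(data[, nm])
  } else if (is.numeric(data) && length(data) == 5) {
    X <- matrix(data, 1L, 5L)
  } else {
    abort("cannot interpret `data` as site-pattern counts",
          class = "coaltrio_domain_error")
  }
  colnames(X) <- pattern_names()
  X
}

dataset_n <- function(data, default = NA_real_) {
  n <- attr(data, "n")
  if (is.null(n)) default else n
}

#' Realize a three-sequence alignment from site-pattern counts
#'
#' Expands a 5-vector of site-pattern counts into three nucleotide sequences
#' (labelled `a`, `b`, `c` for species A, B, C) whose per-site pattern classes
#' reproduce the counts exactly. Base identities are assigned uniformly at
#' random among the assignments consistent with each pattern, and site order
#' is shuffled.
#'
#' @param counts Named or ordered 5-vector of counts (`xxx`, `xxy`, `yxx`,
#'   `xyx`, `xyz`), or a one-row dataset tibble.
#' @param seed Integer seed for the base assignments and site order.
#' @return A character matrix with rows `a`, `b`, `c` and one column per site.
#' @examples
#' aln <- realize_alignment(c(xxx = 3, xxy = 1, yxx = 0, xyx = 0, xyz = 1))
#' alignment_to_counts(aln)
#' @export
realize_alignment <- function(counts, seed = 1L) {
  x <- as.integer(counts_matrix(counts)[1L, ])
  n <- sum(x)
  bases <- c("T", "C", "A", "G")
  with_rng(seed, {
    pat <- rep.int(1:5, x)
    m <- matrix("", 3L, n)
    for (i in seq_len(n)) {
      tri <- switch(pat[i],
        rep(sample(bases, 1L), 3L),                          # xxx
        { b2 <- sample(bases, 2L); c(b2[1], b2[1], b2[2]) }, # xxy
        { b2 <- sample(bases, 2L); c(b2[2], b2[1], b2[1]) }, # yxx
        { b2 <- sample(bases, 2L); c(b2[1], b2[2], b2[1]) }, # xyx
        sample(bases, 3L))                                   # xyz
      m[, i] <- tri
    }
    m <- m[, sample.int(n), drop = FALSE]
    rownames(m) <- c("a", "b", "c")
    m
  })
}

#' Reduce a three-sequence alignment to site-pattern counts
#'
#' @param aln A 3 x n character matrix (rows in species order a, b, c), or an
#'   `ape::DNAbin` alignment with three sequences.
#' @return Named integer 5-vector of pattern counts.
#' @export
alignment_to_counts <- function(aln) {
  if (inherits(aln, "DNAbin")) aln <- toupper(as.character(as.matrix(aln)))
  if (!is.matrix(aln) || nrow(aln) != 3)
    abort("alignment must have exactly three sequences",
          class = "coaltrio_domain_error")
  a <- aln[1, ]; b <- aln[2, ]; c_ <- aln[3, ]
  ab <- a == b; bc <- b == c_; ca <- c_ == a
  pat <- integer(ncol(aln))
  pat[ab & bc] <- 1L            # xxx
  pat[ab & !bc & !ca] <- 2L     # xxy
  pat[bc & !ab & !ca] <- 3L     # yxx
  pat[ca & !ab & !bc] <- 4L     # xyx
  pat[!ab & !bc & !ca] <- 5L    # xyz
  setNames(tabulate(pat, 5L), pattern_names())
}

#' Write a multilocus dataset and its provenance to disk
#'
#' Writes the pattern-count matrix as TSV (columns `locus`, `xxx` .. `xyz`)
#' plus a JSON sidecar with the generating parameters, `m`, `n`, and seed when
#' available.
#'
#' @param data A dataset tibble (e.g. [sim_dataset()]).
#' @param path Output TSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_dataset_tsv <- function(data, path) {
  utils::write.table(as.data.frame(data), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p <- attr(data, "params")
  side <- list(m = nrow(data), n = dataset_n(data),
               seed = attr(data, "seed"))
  if (!is.null(p))
    side$params <- list(tau0 = p$tau0, tau1 = p$tau1,
                        theta0 = p$theta0, theta1 = p$theta1, label = p$label)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a pattern-count TSV written by [write_dataset_tsv()]
#'
#' @param path TSV path. A JSON sidecar `<path>.json`, if present, restores
#'   the `n` and parameter attributes.
#' @return A dataset tibble.
#' @export
read_dataset_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  out <- tibble::as_tibble(df)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "n") <- side$n
    if (!is.null(side$params))
      attr(out, "params") <- msc_params(side$params$tau0, side$params$tau1,
                                        side$params$theta0, side$params$theta1)
    attr(out, "seed") <- side$seed
  }
  class(out) <- c("msc_dataset", class(out))
  out
}

#' Write a realized alignment to FASTA or sequential PHYLIP
#'
#' @param aln A 3 x n character matrix from [realize_alignment()].
#' @param path Output file path.
#' @param format `"fasta"` or `"phylip"` (sequential).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  bin <- ape::as.DNAbin(aln)
  if (format == "fasta") {
    ape::write.FASTA(bin, path)
  } else {
    ape::write.dna(bin, path, format = "sequential", colsep = "",
                   nbcol = -1)
  }
  invisible(path)
}

#' Read a three-sequence alignment (FASTA or PHYLIP) as pattern counts
#'
#' @param path Alignment file path.
#' @param format `"fasta"` or `"phylip"`; guessed from the extension when
#'   missing.
#' @return Named integer 5-vector of site-pattern counts.
#' @export
read_alignment_counts <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(fa|fasta|fas)$", path, ignore.case = TRUE))
      "fasta" else "phylip"
  }
  bin <- if (format == "fasta") ape::read.FASTA(path)
         else ape::read.dna(path, format = "sequential")
  alignment_to_counts(bin)
}

#' Simulate site-pattern counts for a single locus
#'
#' Convenience wrapper around [sim_dataset()] for one locus: draws one gene
#' tree and multinomial site-pattern counts of `n` sites.
#'
#' @inheritParams sim_dataset
#' @return Named integer 5-vector of counts summing to `n`.
#' @export
sim_locus_counts <- function(params, n, seed = 1L) {
  d <- sim_dataset(params, m = 1L, n = n, seed = seed)
  x <- as.integer(counts_matrix(d)[1L, ])
  setNames(x, pattern_names())
}
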