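#' Species-tree parameters for a rooted triplet under the coalescent
#'
#' Bundles the four parameters of the multispecies coalescent (MSC) model for
#' a rooted three-species tree under the molecular clock: the root divergence
#' age `tau0`, the internal divergence age `tau1`, and the population-size
#' parameters `theta0` (root population) and `theta1` (internal ancestral
#' population). All four are measured in expected substitutions per site
#' (theta = 4\*N\*mu). The label identifies which of the three rooted species
#' trees the parameters belong to: S1 = ((A,B),C), S2 = ((B,C),A),
#' S3 = ((C,A),B).
#'
#' @param tau0 Root divergence age, substitutions/site. Must exceed `tau1`.
#' @param tau1 Internal divergence age, substitutions/site, in (0, `tau0`).
#' @param theta0 Root population-size parameter, > 0.
#' @param theta1 Internal ancestral population-size parameter, > 0.
#' @param label Species-tree label, one of `"S1"`, `"S2"`, `"S3"`.
#'
#' @return An object of class `msc_params`: a named list with the four
#'   parameters, the label, and the derived non-coalescence probability `phi`.
#' @examples
#' p <- msc_params(0.02, 0.019, 0.01, 0.05)
#' p$phi
#' gene_tree_topology_probs(p)
#' @export
msc_params <- function(tau0, tau1, theta0, theta1, label = "S1") {
  stopifnot(length(tau0) == 1, length(tau1) == 1,
            length(theta0) == 1, length(theta1) == 1)
  if (!is.finite(tau0) || !is.finite(tau1) || tau1 <= 0 || tau0 < tau1)
    abort("require 0 < tau1 <= tau0 (both finite)", class = "coaltrio_domain_error")
  if (!is.finite(theta0) || theta0 <= 0 || !is.finite(theta1) || theta1 <= 0)
    abort("require theta0 > 0 and theta1 > 0", class = "coaltrio_domain_error")
  label <- match.arg(label, c("S1", "S2", "S3"))
  structure(
    list(tau0 = tau0, tau1 = tau1, theta0 = theta0, theta1 = theta1,
         label = label, phi = exp(-2 * (tau0 - tau1) / theta1)),
    class = "msc_params")
}

#' @export
print.msc_params <- function(x, ...) {
  cat(sprintf("MSC triplet parameters (%s):\n", x$label))
  cat(sprintf("  tau0 = %g, tau1 = %g, theta0 = %g, theta1 = %g\n",
              x$tau0, x$tau1, x$theta0, x$theta1))
  cat(sprintf("  phi (no coalescence in internal population) = %g\n", x$phi))
  invisible(x)
}

as_msc_params <- function(params) {
  if (inherits(params, "msc_params")) return(params)
  if (is.numeric(params) && length(params) == 4 && !is.null(names(params)))
    return(msc_params(params[["tau0"]], params[["tau1"]],
                      params[["theta0"]], params[["theta1"]]))
  if (is.list(params))
    return(msc_params(params$tau0, params$tau1, params$theta0, params$theta1))
  abort("cannot interpret `params` as MSC parameters",
        class = "coaltrio_domain_error")
}

#' Probability that the ingroup lineages fail to coalesce
#'
#' Returns phi = exp(-2 (tau0 - tau1) / theta1), the probability that the two
#' sequences from the sister species do not coalesce in their ancestral
#' population during the interval (tau1, tau0), so that all three lineages
#' enter the root population. The exponent 2 (tau0 - tau1) / theta1 is the
#' internal branch length in coalescent units.
#'
#' @param params An [msc_params()] object (or coercible list).
#' @return A probability in (0, 1\] (equal to 1 when `tau0 == tau1`).
#' @examples
#' noncoalescence_prob(msc_params(0.02, 0.019, 0.01, 0.05))
#' @export
noncoalescence_prob <- function(params) {
  as_msc_params(params)$phi
}

#' Gene-tree topology probabilities given the species tree
#'
#' Probabilities of the three rooted gene-tree topologies G1 = ((a,b),c),
#' G2 = ((b,c),a), G3 = ((c,a),b) for one locus given species tree S1:
#' P(G1) = 1 - (2/3) phi and P(G2) = P(G3) = phi / 3, where phi is the
#' non-coalescence probability of [noncoalescence_prob()].
#'
#' @inheritParams noncoalescence_prob
#' @return Named numeric vector `c(G1 = , G2 = , G3 = )` summing to 1.
#' @examples
#' gene_tree_topology_probs(msc_params(0.02, 0.019, 0.01, 0.05))
#' @export
gene_tree_topology_probs <- function(params) {
  phi <- as_msc_params(params)$phi
  c(G1 = 1 - 2 * phi / 3, G2 = phi / 3, G3 = phi / 3)
}

#' Convert the internal branch to coalescent units
#'
#' @inheritParams noncoalescence_prob
#' @return The internal branch length 2 (tau0 - tau1) / theta1 in coalescent
#'   units (mean coalescent times in the ancestral population).
#' @export
internal_branch_coalescent_units <- function(params) {
  p <- as_msc_params(params)
  2 * (p$tau0 - p$tau1) / p$theta1
}

#' Read MSC parameters from a plain-text configuration file
#'
#' Accepts either a YAML file or simple `key = value` lines; keys `tau0`,
#' `tau1`, `theta0`, `theta1` are required, `label` is optional.
#'
#' @param path Path to the configuration file.
#' @return An [msc_params()] object.
#' @export
read_msc_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- grep("^\\s*[A-Za-z0-9_]+\\s*[:=]", lines, value = TRUE)
  vals <- list()
  for (ln in kv) {
    parts <- strsplit(sub("#.*$", "", ln), "[:=]")[[1]]
    if (length(parts) < 2) next
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = ":"))
    vals[[key]] <- val
  }
  need <- c("tau0", "tau1", "theta0", "theta1")
  if (!all(need %in% names(vals)))
    abort(paste("config must define", paste(need, collapse = ", ")),
          class = "coaltrio_domain_error")
  msc_params(as.numeric(vals$tau0), as.numeric(vals$tau1),
             as.numeric(vals$theta0), as.numeric(vals$theta1),
             label = if (is.null(vals$label)) "S1" else vals$label)
}
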