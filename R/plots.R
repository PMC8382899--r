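# ggplot2 diagnostics.

#' Plot species-tree error sweeps
#'
#' Plots error estimates or predictions against the number of loci, optionally
#' on the probit scale on which the theory predicts a straight line in
#' sqrt(m).
#'
#' @param estimates Tibble with columns `m`, `error`, and optionally `method`.
#' @param probit If `TRUE`, plot qnorm(error) against sqrt(m).
#' @return A ggplot object.
#' @export
plot_error_sweep <- function(estimates, probit = FALSE) {
  df <- tibble::as_tibble(estimates)
  if (is.null(df$method)) df$method <- "error"
  if (probit) {
    df <- df[df$error > 0 & df$error < 1, , drop = FALSE]
    ggplot2::ggplot(df, ggplot2::aes(sqrt(.data$m), qnorm(.data$error),
                                     colour = .data$method)) +
      ggplot2::geom_point() +
      ggplot2::geom_line() +
      ggplot2::labs(x = expression(sqrt(m)),
                    y = expression(Phi^-1 * (e)),
                    colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$m, .data$error,
                                     colour = .data$method)) +
      ggplot2::geom_point() +
      ggplot2::geom_line() +
      ggplot2::labs(x = "loci (m)", y = "species-tree error", colour = NULL) +
      ggplot2::theme_minimal()
  }
}

#' @method autoplot probit_fit
#' @export
autoplot.probit_fit <- function(object, ...) {
  df <- object$data
  ggplot2::ggplot(df, ggplot2::aes(.data$sqrt_m, .data$probit)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, colour = "steelblue") +
    ggplot2::labs(x = expression(sqrt(m)), y = expression(Phi^-1 * (e)),
                  subtitle = sprintf("R^2 = %.4f", object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @method autoplot gene_tree_recovery
#' @export
autoplot.gene_tree_recovery <- function(object, ...) {
  df <- tibble::tibble(
    outcome = factor(c("G1", "G2", "G3", "tie"),
                     levels = c("G1", "G2", "G3", "tie")),
    probability = c(object$g1, object$g2, object$g3, object$p_tie))
  ggplot2::ggplot(df, ggplot2::aes(.data$outcome, .data$probability)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "probability",
                  subtitle = paste("estimated-gene-tree distribution,",
                                   object$mode)) +
    ggplot2::theme_minimal()
}
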