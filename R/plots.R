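#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted dose-response curve
#'
#' Observed survival fractions with the fitted 4PL curve on a log10 dose
#' axis; the IC50 is marked.
#'
#' @param object A `fourpl_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fourpl_fit <- function(object, ...) {
  obs <- tibble::tibble(dose = object$doses, fraction = object$fractions)
  grid <- 10^seq(log10(min(object$doses)), log10(max(object$doses)),
                 length.out = 200)
  curve <- tibble::tibble(dose = grid, fraction = predict(object, grid))
  ggplot2::ggplot(obs, ggplot2::aes(.data$dose, .data$fraction)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$ic50_hat, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose", y = "survival fraction",
                  title = sprintf("4PL fit: IC50 = %.3g", object$ic50_hat)) +
    ggplot2::theme_minimal()
}

#' Plot a growth fit
#'
#' @param object A `growth_fit`.
#' @param data The normalized counts used for the fit (columns `hours`,
#'   `norm_count`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.growth_fit <- function(object, data, ...) {
  p <- ggplot2::ggplot(data, ggplot2::aes(.data$hours, .data$norm_count)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = "hours", y = "normalized count (log2)") +
    ggplot2::theme_minimal()
  if (!object$no_growth) {
    p <- p +
      ggplot2::geom_abline(slope = object$slope, intercept = 0,
                           colour = "steelblue") +
      ggplot2::ggtitle(sprintf("PDT = %.2f h (CI95 %.2f-%.2f)",
                               object$pdt_hat, object$ci95[1], object$ci95[2]))
  }
  p
}

#' Plot a consensus signature
#'
#' Bar chart of consensus scores, colored by direction of association with
#' treatment response where available.
#'
#' @param object A `consensus_signature`.
#' @param top_n Show at most this many proteins (default 30).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.consensus_signature <- function(object, top_n = 30, ...) {
  df <- utils::head(tibble::as_tibble(object), top_n)
  df$protein_id <- factor(df$protein_id, levels = rev(df$protein_id))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$score, .data$protein_id))
  if ("direction" %in% names(df)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$direction)) +
      ggplot2::scale_fill_manual(
        values = c(poorer = "firebrick", better = "steelblue"))
  } else {
    p <- p + ggplot2::geom_col(fill = "grey40")
  }
  p + ggplot2::labs(x = "consensus score", y = NULL,
                    title = "Consensus protein signature") +
    ggplot2::theme_minimal()
}

#' Plot per-size RMSE profiles of an ensemble
#'
#' @param object An `rfe_ensemble`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rfe_ensemble <- function(object, ...) {
  df <- purrr::imap_dfr(object, function(r, i)
    dplyr::mutate(r$rmse_profile, run = i))
  ggplot2::ggplot(df, ggplot2::aes(.data$size, .data$rmse,
                                   group = .data$run)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "subset size", y = "cross-validated RMSE",
                  title = "Backward-elimination RMSE profiles") +
    ggplot2::theme_minimal()
}
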