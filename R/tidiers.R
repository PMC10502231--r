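#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a 4PL dose-response fit
#' @param x A `fourpl_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.fourpl_fit <- function(x, ...) {
  tibble::tibble(
    term = c("top", "bottom", "ic50", "hill"),
    estimate = c(x$top, x$bottom, x$ic50_hat, x$hill))
}

#' @rdname tidy.fourpl_fit
#' @export
glance.fourpl_fit <- function(x, ...) {
  tibble::tibble(
    ic50_hat = x$ic50_hat,
    ic50_lo = if (is.null(x$ci95_ic50)) NA_real_ else x$ci95_ic50[1],
    ic50_hi = if (is.null(x$ci95_ic50)) NA_real_ else x$ci95_ic50[2],
    hill = x$hill, top = x$top, bottom = x$bottom,
    rss = x$rss, n_points = x$n_points, converged = x$converged)
}

#' Tidy a doubling-time fit
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(term = c("pdt_hours", "slope_log2_per_hour"),
                 estimate = c(x$pdt_hat, x$slope))
}

#' @rdname tidy.growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(pdt_hat = x$pdt_hat, pdt_lo = x$ci95[1], pdt_hi = x$ci95[2],
                 slope = x$slope, r_squared = x$r_squared,
                 n_points = x$n_points, no_growth = x$no_growth)
}

#' Tidy a two-strata stratification
#' @param x A `strata_result`.
#' @param ... Unused.
#' @return The per-clone group assignment tibble.
#' @export
tidy.strata_result <- function(x, ...) x$groups

#' @rdname tidy.strata_result
#' @export
glance.strata_result <- function(x, ...) {
  tibble::tibble(cutoff = x$cutoff, objective_value = x$objective_value,
                 n_resG = x$n_resG, n_sensG = x$n_sensG)
}

#' Tidy a backward-elimination run
#' @param x An `rfe_run`.
#' @param ... Unused.
#' @return One row per selected protein: `rank`, `protein_id`,
#'   `contribution`.
#' @export
tidy.rfe_run <- function(x, ...) {
  tibble::tibble(rank = seq_along(x$selected), protein_id = x$selected,
                 contribution = per_run_contribution(seq_along(x$selected),
                                                     x$b))
}

#' @rdname tidy.rfe_run
#' @export
glance.rfe_run <- function(x, ...) {
  tibble::tibble(seed = x$seed, b = x$b, best_rmse = x$best_rmse,
                 best_size = x$best_size)
}
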