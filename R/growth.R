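#' Normalize growth counts to day 1
#'
#' Divides each replicate's count series by that replicate's own day-1
#' count, so every series starts at 1 on day 1.
#'
#' @param counts Tibble from [simulate_growth()] or user data: columns
#'   `day`, `bio_rep`, `count`, optionally `clone` and `hours` (filled as
#'   `24 * day` when absent).
#' @return The input with an added `norm_count` column.
#' @export
normalize_to_day1 <- function(counts) {
  req <- c("day", "bio_rep", "count")
  if (!all(req %in% names(counts)))
    stop("counts must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!"hours" %in% names(counts)) counts$hours <- 24 * counts$day
  keys <- intersect(c("clone", "bio_rep"), names(counts))

  out <- counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::mutate(.day1 = .data$count[match(1, .data$day)]) |>
    dplyr::ungroup()
  if (any(is.na(out$.day1)))
    stop("day-1 count missing for at least one replicate", call. = FALSE)
  if (any(out$.day1 <= 0))
    stop("nonpositive day-1 count", call. = FALSE)
  out |>
    dplyr::mutate(norm_count = .data$count / .data$.day1) |>
    dplyr::select(-".day1")
}

#' Estimate population doubling time from normalized counts
#'
#' Ordinary least squares of `log2(normalized count)` on time in hours,
#' pooling all replicates into a single regression. The doubling time is
#' the reciprocal of the slope (hours per log2 doubling); its 95% CI is the
#' slope's t-based CI mapped through the reciprocal (a monotone transform).
#' A nonpositive estimated slope is flagged as no growth and no doubling
#' time is reported.
#'
#' @param normalized Tibble with columns `hours` and `norm_count` (see
#'   [normalize_to_day1()]); if `norm_count` is absent but `count` present,
#'   counts are normalized first.
#' @param per_replicate If `TRUE`, fit each biological replicate separately
#'   and average the resulting doubling times (CI from the t-distribution
#'   of the replicate estimates) instead of pooling.
#' @return An object of class `growth_fit`: `pdt_hat` (h), `ci95` (h),
#'   `slope` (log2 per hour), `r_squared`, `n_points`, `no_growth` flag.
#' @examples
#' g <- simulate_growth(builtin_presets("B2D9"), n_days = 5, seed = 3)
#' fit_pdt(normalize_to_day1(g))
#' @export
fit_pdt <- function(normalized, per_replicate = FALSE) {
  if (!"norm_count" %in% names(normalized))
    normalized <- normalize_to_day1(normalized)
  stopifnot(all(c("hours", "norm_count") %in% names(normalized)))
  if (length(unique(normalized$hours)) < 3)
    stop("at least 3 time points are required", call. = FALSE)
  if (any(normalized$norm_count <= 0))
    stop("nonpositive normalized counts", call. = FALSE)

  fit_one <- function(df) {
    # noise-free inputs give an exactly perfect fit; the resulting
    # "essentially perfect fit" summary warning is expected, not actionable
    withCallingHandlers({
      m <- stats::lm(log2(norm_count) ~ hours, data = df)
      slope <- unname(stats::coef(m)["hours"])
      ci_slope <- stats::confint(m, "hours", level = 0.95)
      list(slope = slope, ci_slope = as.numeric(ci_slope),
           r2 = summary(m)$r.squared, n = nrow(df))
    }, warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  }

  if (per_replicate) {
    parts <- normalized |>
      dplyr::group_split(.data$bio_rep) |>
      purrr::map(fit_one)
    slopes <- purrr::map_dbl(parts, "slope")
    if (any(slopes <= 0)) {
      warning("no growth: nonpositive slope in at least one replicate")
      return(.growth_fit_no_growth(mean(slopes), nrow(normalized)))
    }
    pdts <- 1 / slopes
    se <- stats::sd(pdts) / sqrt(length(pdts))
    tq <- stats::qt(0.975, df = length(pdts) - 1)
    return(structure(
      list(pdt_hat = mean(pdts), ci95 = mean(pdts) + c(-1, 1) * tq * se,
           slope = mean(slopes), r_squared = mean(purrr::map_dbl(parts, "r2")),
           n_points = nrow(normalized), no_growth = FALSE,
           pooled = FALSE),
      class = "growth_fit"))
  }

  f <- fit_one(normalized)
  if (f$slope <= 0) {
    warning("no growth: estimated slope is nonpositive")
    return(.growth_fit_no_growth(f$slope, f$n))
  }
  # reciprocal is decreasing: upper slope bound -> lower PDT bound
  ci <- if (all(f$ci_slope > 0)) sort(1 / f$ci_slope) else c(0, Inf)
  structure(
    list(pdt_hat = 1 / f$slope, ci95 = ci, slope = f$slope,
         r_squared = f$r2, n_points = f$n, no_growth = FALSE, pooled = TRUE),
    class = "growth_fit")
}

.growth_fit_no_growth <- function(slope, n) {
  structure(
    list(pdt_hat = NA_real_, ci95 = c(NA_real_, NA_real_), slope = slope,
         r_squared = NA_real_, n_points = n, no_growth = TRUE, pooled = TRUE),
    class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  if (x$no_growth) {
    cat("<growth_fit> NO GROWTH (slope =", signif(x$slope, 3), ")\n")
  } else {
    cat(sprintf("<growth_fit> PDT = %.2f h  (CI95: %.2f - %.2f h)  R2 = %.3f  n = %d\n",
                x$pdt_hat, x$ci95[1], x$ci95[2], x$r_squared, x$n_points))
  }
  invisible(x)
}
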