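#' Two-strata responder stratification
#'
#' Splits a set of per-clone response values (survival fractions under
#' treatment) into a more-resistant and a more-sensitive group by
#' exhaustive search over all candidate cutoffs — the midpoints of
#' consecutive distinct sorted values — minimizing the weighted
#' within-stratum dispersion
#' \deqn{\sum_h W_h S_h, \quad W_h = n_h / n, \; S_h = \mathrm{sd}_h,}
#' the criterion of classical optimal-stratification methods. At the panel
#' sizes typical of clone screens (n = 12-14) the exhaustive scan is exact
#' and distribution-free. Ties in the objective resolve to the smallest
#' cutoff; singleton strata have dispersion 0.
#'
#' @param responses Numeric vector of responses in any order, or a data
#'   frame with columns `clone` and `response`.
#' @return An object of class `strata_result`: `cutoff`, `objective_value`,
#'   `groups` (tibble `clone`, `response`, `group`), `n_resG`, `n_sensG`.
#'   Responses above the cutoff are `resG` (higher survival = more
#'   resistant); values equal to the cutoff fall in `sensG`.
#' @examples
#' fit_two_strata(c(0.1, 0.1, 0.9, 0.9))
#' @export
fit_two_strata <- function(responses) {
  if (is.data.frame(responses)) {
    stopifnot(all(c("clone", "response") %in% names(responses)))
    clones <- responses$clone
    x <- responses$response
  } else {
    x <- as.numeric(responses)
    clones <- names(responses) %||% sprintf("clone_%02d", seq_along(x))
  }
  stopifnot(all(is.finite(x)))
  ux <- sort(unique(x))
  if (length(x) < 4 || length(ux) < 2)
    stop("at least 4 response values (>= 2 distinct) are required",
         call. = FALSE)
  if (stats::sd(x) == 0)
    stop("zero overall variance", call. = FALSE)

  candidates <- (ux[-length(ux)] + ux[-1]) / 2
  obj <- vapply(candidates, .strata_objective, numeric(1), x = x)
  best <- which.min(obj)  # ties -> smallest cutoff

  cutoff <- candidates[best]
  groups <- assign_groups(stats::setNames(x, clones), cutoff)
  structure(
    list(cutoff = cutoff, objective_value = obj[best], groups = groups,
         n_resG = sum(groups$group == "resG"),
         n_sensG = sum(groups$group == "sensG"),
         candidates = tibble::tibble(cutoff = candidates, objective = obj)),
    class = "strata_result")
}

.strata_objective <- function(cutoff, x) {
  lo <- x[x <= cutoff]
  hi <- x[x > cutoff]
  sd0 <- function(v) if (length(v) < 2) 0 else stats::sd(v)
  (length(lo) * sd0(lo) + length(hi) * sd0(hi)) / length(x)
}

#' @export
print.strata_result <- function(x, ...) {
  cat(sprintf("<strata_result> cutoff = %.4g  objective = %.4g  (resG: %d, sensG: %d)\n",
              x$cutoff, x$objective_value, x$n_resG, x$n_sensG))
  invisible(x)
}

#' Assign clones to responder groups at a given cutoff
#'
#' Responses strictly above the cutoff are labelled `resG` (more
#' resistant); responses at or below it `sensG` (boundary values go to the
#' sensitive group). A warning is emitted when one group is empty.
#'
#' @param responses Named numeric vector or data frame with `clone` and
#'   `response` columns.
#' @param cutoff Finite response cutoff.
#' @return Tibble with columns `clone`, `response`, `group`.
#' @export
assign_groups <- function(responses, cutoff) {
  stopifnot(is.finite(cutoff))
  if (is.data.frame(responses)) {
    clones <- responses$clone
    x <- responses$response
  } else {
    x <- as.numeric(responses)
    clones <- names(responses) %||% sprintf("clone_%02d", seq_along(x))
  }
  group <- ifelse(x > cutoff, "resG", "sensG")
  if (all(group == "resG")) warning("all clones fall in resG")
  if (all(group == "sensG")) warning("all clones fall in sensG")
  tibble::tibble(clone = clones, response = x, group = group)
}

#' Correlation between two response measurements
#'
#' Pearson correlation (with two-sided test) between per-clone responses
#' measured under two conditions, e.g. at the parental IC50 and at the
#' parental ICmax.
#'
#' @param respA,respB Equal-length numeric vectors (>= 3 values).
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @export
response_correlation <- function(respA, respB) {
  stopifnot(length(respA) == length(respB), length(respA) >= 3)
  if (stats::sd(respA) == 0 || stats::sd(respB) == 0)
    stop("zero variance in at least one response vector", call. = FALSE)
  ct <- stats::cor.test(respA, respB, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(respA))
}
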