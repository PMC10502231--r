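#' Per-run rank contribution to the consensus score
#'
#' A protein ranked `a` (1 = most important) in a run whose optimal set
#' holds `b` proteins contributes
#' \deqn{X_k = 1 - \frac{a - 1}{b}}
#' to its total score: 1 for the top rank, down to 1/b for the last listed
#' protein. Proteins absent from a run contribute nothing.
#'
#' @param a Rank position(s) within the run, `1 <= a <= b`.
#' @param b Size(s) of the run's selected set.
#' @return Numeric contribution(s) in `(0, 1]`.
#' @examples
#' per_run_contribution(1, 10)   # 1
#' per_run_contribution(3, 4)    # 0.5
#' @export
per_run_contribution <- function(a, b) {
  stopifnot(length(a) == length(b) || length(a) == 1L || length(b) == 1L)
  if (any(a < 1) || any(a > b))
    stop("rank a must satisfy 1 <= a <= b", call. = FALSE)
  1 - (a - 1) / b
}

#' Consensus scores across ensemble runs
#'
#' Integrates the per-run selected protein sets of an ensemble into one
#' total score per protein: the sum over runs, for runs containing the
#' protein, of [per_run_contribution()] at the protein's rank in that run.
#' Scores lie in `(0, n_runs]`; a protein reaches `n_runs` only by ranking
#' first in every run. Proteins selected in no run are omitted.
#'
#' @param runs An `rfe_ensemble` or plain list of `rfe_run` objects.
#' @return Tibble with columns `protein_id`, `score`, `runs_appeared`,
#'   `mean_contribution` (score / runs_appeared), sorted by descending
#'   score.
#' @export
consensus_scores <- function(runs) {
  if (inherits(runs, "rfe_run")) runs <- list(runs)
  stopifnot(length(runs) >= 1)
  per_run <- purrr::map_dfr(runs, function(r) {
    tibble::tibble(protein_id = r$selected,
                   contribution = per_run_contribution(
                     seq_along(r$selected), r$b))
  })
  per_run |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(score = sum(.data$contribution),
                     runs_appeared = dplyr::n(),
                     mean_contribution = mean(.data$contribution),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$protein_id)
}

#' Finalize a consensus protein signature
#'
#' Orders proteins by descending total score — ties broken by higher mean
#' per-run contribution, then lexicographic protein id, so the order is
#' deterministic — truncates at `cap`, and annotates each protein's
#' direction of association with treatment response via
#' [annotate_direction()].
#'
#' @param scores Tibble from [consensus_scores()], or an `rfe_ensemble`
#'   (scored internally).
#' @param cap Maximum signature length (default 50).
#' @param pm The [proteome_matrix] the ensemble was run on (used for
#'   direction annotation); optional — without it, directions are omitted.
#' @param n_runs Number of ensemble runs (inferred from an `rfe_ensemble`).
#' @return An object of class `consensus_signature`: tibble with columns
#'   `rank`, `protein_id`, `score`, `runs_appeared`, `mean_contribution`,
#'   and (given `pm`) `direction` and `rho`; attributes `n_runs`, `cap`,
#'   `n_scored` (size of the scored union).
#' @export
finalize_signature <- function(scores, cap = 50L, pm = NULL, n_runs = NULL) {
  if (cap < 1) stop("cap must be >= 1", call. = FALSE)
  if (inherits(scores, "rfe_ensemble")) {
    n_runs <- n_runs %||% length(scores)
    scores <- consensus_scores(scores)
  }
  if (nrow(scores) == 0) stop("empty scores", call. = FALSE)

  ranked <- scores |>
    dplyr::arrange(dplyr::desc(.data$score),
                   dplyr::desc(.data$mean_contribution),
                   .data$protein_id) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  final <- utils::head(ranked, cap)

  if (!is.null(pm)) {
    dir <- annotate_direction(pm, final$protein_id)
    final <- dplyr::left_join(final, dir, by = "protein_id")
  }
  structure(final, class = c("consensus_signature", class(final)),
            n_runs = n_runs, cap = as.integer(cap), n_scored = nrow(scores))
}

#' @export
print.consensus_signature <- function(x, ...) {
  cat("<consensus_signature> ", nrow(x), " proteins (scored union ",
      attr(x, "n_scored"), ", cap ", attr(x, "cap"),
      if (!is.null(attr(x, "n_runs"))) paste0(", ", attr(x, "n_runs"), " runs"),
      ")\n", sep = "")
  NextMethod()
}

#' Direction of association between protein abundance and response
#'
#' Labels each protein by the sign of the Spearman correlation between its
#' intensity and the per-sample survival fraction: a positive correlation
#' (more abundant in clones that survive treatment better, i.e. resist it)
#' marks the protein as associated with a *poorer* response to treatment;
#' a negative correlation with a *better* response. A numerically zero
#' correlation is labelled `better` and flagged via `zero_assoc`.
#'
#' @param pm A [proteome_matrix].
#' @param proteins Character vector of protein ids present in `pm`.
#' @return Tibble with columns `protein_id`, `rho`, `direction`
#'   (`"poorer"` / `"better"`), `zero_assoc`.
#' @export
annotate_direction <- function(pm, proteins) {
  stopifnot(inherits(pm, "proteome_matrix"))
  missing_ids <- setdiff(proteins, rownames(pm$intensities))
  if (length(missing_ids))
    stop("proteins not in matrix: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  purrr::map_dfr(proteins, function(pid) {
    v <- pm$intensities[pid, ]
    keep <- !is.na(v)
    if (stats::sd(v[keep]) == 0)
      stop("constant intensity vector for protein ", pid, call. = FALSE)
    rho <- stats::cor(v[keep], pm$response[keep], method = "spearman")
    tibble::tibble(protein_id = pid, rho = rho,
                   direction = if (rho > 0) "poorer" else "better",
                   zero_assoc = rho == 0)
  })
}
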