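#' Simulate daily cell counts under exponential growth
#'
#' Cells seeded at `n0` grow exponentially with the preset's true
#' population doubling time and are counted every 24 hours, starting 24 h
#' after seeding (day 1). Expected count at day `d` is
#' `n0 * 2^(24 d / pdt_true)`; each count gets independent multiplicative
#' Gaussian noise. Three biological replicates per time point by default.
#'
#' @param preset A [clone_preset]; its `pdt_true` drives the kinetics.
#' @param n_days Number of daily counts (>= 3).
#' @param n0 Seeded cell number per well.
#' @param config A [sim_config]; `n_bio_reps` replicates per day. The count
#'   noise defaults to a 10% CV, typical of haemocytometer counting; pass
#'   `noise_cv` to override.
#' @param noise_cv Coefficient of variation of the counting noise
#'   (default 0.10).
#' @param seed Optional seed overriding `config$seed`.
#' @return A tibble with columns `clone`, `day`, `hours`, `bio_rep`,
#'   `count`.
#' @examples
#' simulate_growth(builtin_presets("B2D9"), n_days = 5, seed = 3)
#' @export
simulate_growth <- function(preset, n_days = 5L, n0 = 20000,
                            config = sim_config(), noise_cv = 0.10,
                            seed = NULL) {
  stopifnot(inherits(preset, "clone_preset"), n_days >= 3, n0 > 0)
  if (preset$pdt_true <= 0) stop("nonpositive pdt_true", call. = FALSE)

  withr::with_seed(seed %||% config$seed, {
    grid <- tidyr::expand_grid(day = seq_len(n_days),
                               bio_rep = seq_len(config$n_bio_reps))
    hours <- 24 * grid$day
    expected <- n0 * 2^(hours / preset$pdt_true)
    tibble::tibble(
      clone = preset$name,
      day = grid$day,
      hours = hours,
      bio_rep = grid$bio_rep,
      count = expected * .mult_noise(nrow(grid), noise_cv)
    )
  })
}
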