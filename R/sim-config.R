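#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data module in one validated
#' object. All simulators are byte-identical under a fixed `seed`.
#'
#' @param seed Integer RNG seed.
#' @param n_tech_reps Technical replicate wells per condition (default 3).
#' @param n_bio_reps Independent biological repeats (default 3); each
#'   carries its own untreated control wells.
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   well noise (default 0.05, typical for resazurin-based viability
#'   readouts).
#' @param dose_grid Optional concentration series; when `NULL` the
#'   drug-specific [default_dose_grid()] is used.
#' @param control_level Expected raw signal of an untreated well
#'   (arbitrary fluorescence units).
#' @param missing_rate Target overall fraction of missing proteome
#'   entries (default 0.1); missingness is abundance-dependent.
#' @param n_samples,n_proteins,n_planted Proteome dimensions: clone
#'   samples, proteins, and planted response-associated proteins.
#' @param effect_size Log2-intensity shift per unit response for planted
#'   proteins (default 1).
#' @param response_range Interval the per-sample survival-fraction
#'   response is drawn from, default `c(0.25, 0.85)`.
#' @param baseline_mean_log2,baseline_sd_log2 Log-normal baseline of
#'   protein abundance: mean and SD of per-protein log2 intensities.
#' @param proteome_noise_sd Residual per-entry SD in log2 units (default
#'   0.15, about an 11% CV — the technical precision of MaxLFQ-style DIA
#'   quantification; residual variation unrelated to the response is kept
#'   at this level so that a unit planted effect is detectable at n = 12,
#'   the regime the planted-truth design emulates).
#' @return A list with class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_tech_reps = 3L,
                       n_bio_reps = 3L,
                       noise_cv = 0.05,
                       dose_grid = NULL,
                       control_level = 10000,
                       missing_rate = 0.1,
                       n_samples = 12L,
                       n_proteins = 300L,
                       n_planted = 15L,
                       effect_size = 1,
                       response_range = c(0.25, 0.85),
                       baseline_mean_log2 = 18,
                       baseline_sd_log2 = 2.2,
                       proteome_noise_sd = 0.15) {
  stopifnot(
    is.numeric(seed), length(seed) == 1L,
    n_tech_reps >= 1L, n_bio_reps >= 1L,
    noise_cv >= 0,
    missing_rate >= 0, missing_rate < 1,
    n_samples >= 1L, n_proteins >= 1L,
    n_planted >= 0L, n_planted <= n_proteins,
    length(response_range) == 2L, response_range[1] <= response_range[2],
    proteome_noise_sd >= 0, control_level > 0
  )
  if (!is.null(dose_grid)) {
    stopifnot(length(dose_grid) > 0, all(dose_grid > 0),
              !is.unsorted(dose_grid))
  }
  structure(
    list(seed = as.integer(seed), n_tech_reps = as.integer(n_tech_reps),
         n_bio_reps = as.integer(n_bio_reps), noise_cv = noise_cv,
         dose_grid = dose_grid, control_level = control_level,
         missing_rate = missing_rate, n_samples = as.integer(n_samples),
         n_proteins = as.integer(n_proteins), n_planted = as.integer(n_planted),
         effect_size = effect_size, response_range = response_range,
         baseline_mean_log2 = baseline_mean_log2,
         baseline_sd_log2 = baseline_sd_log2,
         proteome_noise_sd = proteome_noise_sd),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed,
      "| reps", x$n_tech_reps, "x", x$n_bio_reps,
      "| noise_cv", x$noise_cv,
      "| proteome", x$n_proteins, "x", x$n_samples,
      "(", x$n_planted, "planted, effect", x$effect_size, ")\n")
  invisible(x)
}

# multiplicative Gaussian noise factors, CV = cv
.mult_noise <- function(n, cv) {
  if (cv == 0) rep(1, n) else stats::rnorm(n, mean = 1, sd = cv)
}
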