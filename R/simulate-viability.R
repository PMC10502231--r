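#' Simulate a full dose-response viability plate
#'
#' Emulates a CellTiter-Blue-style viability experiment for one clone and
#' one drug: for each biological repeat, `n_tech_reps` untreated control
#' wells plus `n_tech_reps` treated wells per dose. The expected treated
#' signal is `control_level * fourpl(dose; preset)`; every well receives
#' independent multiplicative Gaussian noise with coefficient of variation
#' `noise_cv`.
#'
#' @param preset A [clone_preset] with parameters for `drug`.
#' @param drug Drug label, must be present in `preset$drug_params`.
#' @param config A [sim_config]; `config$dose_grid`, if `NULL`, falls back
#'   to [default_dose_grid()] for the drug.
#' @param seed Optional seed overriding `config$seed`.
#' @return A tibble in long plate format with columns `clone`, `drug`,
#'   `dose` (0 for control wells), `bio_rep`, `tech_rep`, `treated`
#'   (logical), `signal`.
#' @examples
#' plate <- simulate_viability_plate(builtin_presets("parental_BxPC3"),
#'                                   "gemcitabine", sim_config(seed = 1))
#' dplyr::count(plate, treated)
#' @export
simulate_viability_plate <- function(preset, drug, config = sim_config(),
                                     seed = NULL) {
  stopifnot(inherits(preset, "clone_preset"), inherits(config, "sim_config"))
  if (!drug %in% names(preset$drug_params)) {
    stop("preset '", preset$name, "' has no parameters for drug '", drug, "'",
         call. = FALSE)
  }
  doses <- config$dose_grid %||% default_dose_grid(drug)
  if (length(doses) == 0) stop("empty dose grid", call. = FALSE)
  stopifnot(all(doses > 0), !is.unsorted(doses))
  dp <- preset$drug_params[[drug]]

  withr::with_seed(seed %||% config$seed, {
    grid <- tidyr::expand_grid(
      bio_rep = seq_len(config$n_bio_reps),
      dose = c(0, doses),
      tech_rep = seq_len(config$n_tech_reps)
    )
    expected <- ifelse(
      grid$dose == 0,
      config$control_level,
      config$control_level *
        fourpl(pmax(grid$dose, .Machine$double.eps), dp$top, dp$bottom,
               dp$ic50_true, dp$hill)
    )
    tibble::tibble(
      clone = preset$name,
      drug = drug,
      dose = grid$dose,
      bio_rep = grid$bio_rep,
      tech_rep = grid$tech_rep,
      treated = grid$dose > 0,
      signal = expected * .mult_noise(nrow(grid), config$noise_cv)
    )
  })
}

#' Simulate a clone panel treated at a single dose
#'
#' Emulates the screening step in which every clone of a panel is treated
#' at one fixed concentration (typically the IC50 or ICmax of the parental
#' population) alongside untreated controls. The expected survival fraction
#' of each clone is taken from its preset's `survival_mean` table.
#'
#' @param presets A list of [clone_preset] objects (or a single preset).
#' @param drug Drug label.
#' @param dose Treatment concentration; every preset must carry a
#'   `survival_mean` entry for `(drug, dose)`.
#' @param config A [sim_config].
#' @param seed Optional seed overriding `config$seed`.
#' @return A tibble in the same long plate format as
#'   [simulate_viability_plate()].
#' @examples
#' panel <- simulate_clone_panel(builtin_presets()[c("B2D9", "B3C10")],
#'                               "gemcitabine", dose = 9.6,
#'                               sim_config(seed = 7))
#' @export
simulate_clone_panel <- function(presets, drug, dose, config = sim_config(),
                                 seed = NULL) {
  if (inherits(presets, "clone_preset")) presets <- list(presets)
  stopifnot(length(presets) >= 1, dose > 0, inherits(config, "sim_config"))

  surv <- purrr::map_dbl(presets, function(p) {
    hit <- p$survival_mean$drug == drug &
      abs(p$survival_mean$dose - dose) < 1e-9 * max(dose, 1)
    if (!any(hit)) {
      stop("preset '", p$name, "' has no survival_mean entry for ",
           drug, " at dose ", dose, call. = FALSE)
    }
    p$survival_mean$fraction[which(hit)[1]]
  })

  withr::with_seed(seed %||% config$seed, {
    purrr::map2_dfr(presets, surv, function(p, s) {
      grid <- tidyr::expand_grid(
        bio_rep = seq_len(config$n_bio_reps),
        dose_ = c(0, dose),
        tech_rep = seq_len(config$n_tech_reps)
      )
      expected <- ifelse(grid$dose_ == 0, config$control_level,
                         config$control_level * s)
      tibble::tibble(
        clone = p$name,
        drug = drug,
        dose = grid$dose_,
        bio_rep = grid$bio_rep,
        tech_rep = grid$tech_rep,
        treated = grid$dose_ > 0,
        signal = expected * .mult_noise(nrow(grid), config$noise_cv)
      )
    })
  })
}
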