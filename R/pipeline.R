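#' Configuration for the end-to-end pipeline
#'
#' @param mode `"simulate"` (presets drive the synthetic-data module) or
#'   `"user-data"` (tables are read from `paths`).
#' @param presets Character vector of preset names (simulate mode).
#' @param drugs Drug labels to profile.
#' @param seed Master seed (mandatory in simulate mode).
#' @param n_runs,cap Ensemble settings for signature extraction.
#' @param stratify Run responder stratification on the clone panel?
#' @param out_dir Output directory (created if needed); `NULL` disables
#'   file output.
#' @param paths Named list of input paths for user-data mode
#'   (`matrix`, `response`, and optionally `truth`, `plates`, `counts`).
#' @param proteome_config Optional [sim_config] for the proteome
#'   simulation.
#' @return A list with class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "user-data"),
                            presets = names(builtin_presets()),
                            drugs = "gemcitabine",
                            seed = 1L,
                            n_runs = 30L,
                            cap = 50L,
                            stratify = TRUE,
                            out_dir = NULL,
                            paths = list(),
                            proteome_config = NULL) {
  mode <- match.arg(mode)
  if (mode == "user-data") {
    for (p in unlist(paths))
      if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  } else {
    stopifnot(is.numeric(seed), length(seed) == 1L)
  }
  structure(
    list(mode = mode, presets = presets, drugs = drugs,
         seed = as.integer(seed), n_runs = as.integer(n_runs),
         cap = as.integer(cap), stratify = isTRUE(stratify),
         out_dir = out_dir, paths = paths,
         proteome_config = proteome_config),
    class = "pipeline_config")
}

.config_hash <- function(config) rlang::hash(unclass(config))

.write_report <- function(obj, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, name)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Run the full response-profiling workflow
#'
#' Simulates (or loads) viability plates, growth counts and the clone
#' panel; computes survival fractions; fits 4PL curves per clone and drug
#' with ICmax extraction; fits doubling times; and stratifies the clone
#' panel's survival fractions into responder groups. All outputs carry the
#' config hash and master seed for provenance and the run is idempotent
#' under a fixed seed.
#'
#' @param config A [pipeline_config].
#' @return A list (`response_profile` class) with elements `fits`
#'   (per clone x drug tibble: IC50, CI, ICmax, PDT), `panel_fractions`,
#'   `strata`, `provenance`.
#' @export
run_response_profiling <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$mode != "simulate")
    stop("user-data response profiling expects plate/count tables via ",
         "survival_fractions(), fit_4pl() and fit_pdt() directly; ",
         "run_response_profiling() orchestrates simulate mode",
         call. = FALSE)

  presets <- builtin_presets()[config$presets]
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage: ", what, "] ", conditionMessage(e), call. = FALSE))
  }

  fits <- stage("dose-response", purrr::imap_dfr(presets, function(p, nm) {
    purrr::map_dfr(config$drugs, function(drug) {
      cfg <- sim_config(seed = config$seed + match(nm, names(presets)) * 100 +
                          match(drug, config$drugs))
      plate <- simulate_viability_plate(p, drug, cfg)
      fr <- survival_fractions(plate)
      fit <- fit_4pl(fr$dose, fr$fraction)
      fit <- bootstrap_ic50_ci(fit, B = 200, seed = cfg$seed)
      im <- icmax_from_fit(fit, unique(fr$dose))
      tibble::tibble(clone = nm, drug = drug,
                     ic50_true = p$drug_params[[drug]]$ic50_true,
                     ic50_hat = fit$ic50_hat,
                     ic50_lo = fit$ci95_ic50[1], ic50_hi = fit$ci95_ic50[2],
                     hill = fit$hill, converged = fit$converged,
                     icmax = im$icmax, icmax_reached = im$reached)
    })
  }))

  pdt <- stage("growth", purrr::imap_dfr(presets, function(p, nm) {
    g <- simulate_growth(p, n_days = 5,
                         config = sim_config(seed = config$seed +
                                               match(nm, names(presets))))
    f <- fit_pdt(normalize_to_day1(g))
    tibble::tibble(clone = nm, pdt_true = p$pdt_true, pdt_hat = f$pdt_hat,
                   pdt_lo = f$ci95[1], pdt_hi = f$ci95[2],
                   r_squared = f$r_squared)
  }))
  fits <- dplyr::left_join(fits, pdt, by = "clone")

  # panel at the parental IC50 dose for every preset with a survival_mean
  panel <- stage("clone-panel", {
    drug <- config$drugs[1]
    elig <- purrr::keep(presets, function(p)
      any(p$survival_mean$drug == drug))
    dose <- elig[[1]]$survival_mean$dose[elig[[1]]$survival_mean$drug == drug][1]
    elig <- purrr::keep(elig, function(p)
      any(p$survival_mean$drug == drug & p$survival_mean$dose == dose))
    pl <- simulate_clone_panel(elig, drug, dose,
                               sim_config(seed = config$seed + 7))
    survival_fractions(pl)
  })

  strata <- NULL
  if (config$stratify) {
    strata <- stage("stratify", {
      means <- panel |>
        dplyr::group_by(.data$clone) |>
        dplyr::summarise(response = mean(.data$fraction), .groups = "drop")
      if (length(unique(round(means$response, 10))) >= 4)
        fit_two_strata(means) else NULL
    })
    if (is.null(strata))
      warning("too few distinct panel responses; stratification skipped")
  }

  provenance <- list(config_hash = .config_hash(config), seed = config$seed,
                     mode = config$mode, timestamp = NULL)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(fits, file.path(config$out_dir, "fits.tsv"))
    readr::write_tsv(panel, file.path(config$out_dir, "panel_fractions.tsv"))
    .write_report(c(provenance, list(
      strata = if (!is.null(strata))
        list(cutoff = strata$cutoff, objective = strata$objective_value,
             groups = strata$groups) else NULL)),
      config$out_dir, "response_profile.json")
  }
  structure(list(fits = fits, panel_fractions = panel, strata = strata,
                 provenance = provenance),
            class = "response_profile")
}

#' Run the consensus signature-extraction workflow
#'
#' Simulates or loads the protein intensity matrix and response vector,
#' preprocesses it (presence filter, half-minimum imputation, log2),
#' executes the seeded backward-elimination ensemble, and finalizes the
#' capped, direction-annotated consensus signature. When simulated ground
#' truth is available, a truth-evaluation report (planted-recovery
#' fraction in the signature and in the top-30 ranks) is included.
#'
#' @param config A [pipeline_config]; in user-data mode `paths$matrix` and
#'   `paths$response` are required.
#' @return A list (`signature_result` class): `signature`
#'   (a `consensus_signature`), `ensemble`, `truth_eval` (or `NULL`),
#'   `provenance`.
#' @export
run_signature_extraction <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  pm <- if (config$mode == "simulate") {
    cfg <- config$proteome_config %||% sim_config(seed = config$seed)
    simulate_proteome(cfg)
  } else {
    if (is.null(config$paths$matrix) || is.null(config$paths$response))
      stop("user-data mode needs paths$matrix and paths$response",
           call. = FALSE)
    read_proteome_tsv(config$paths$matrix, config$paths$response,
                      config$paths$truth)
  }

  prep <- preprocess_proteome(pm)
  ens <- run_ensemble(prep, n_runs = config$n_runs,
                      base_seed = config$seed)
  sig <- finalize_signature(ens, cap = config$cap, pm = prep)

  truth_eval <- NULL
  if (!is.null(pm$truth) && nrow(pm$truth$planted)) {
    planted <- pm$truth$planted$protein_id
    ranking <- finalize_signature(consensus_scores(ens),
                                  cap = attr(sig, "n_scored"),
                                  n_runs = config$n_runs)
    top30 <- utils::head(ranking$protein_id, 30)
    truth_eval <- list(
      n_planted = length(planted),
      recovered_in_signature = sum(sig$protein_id %in% planted),
      recovery_fraction = mean(planted %in% sig$protein_id),
      recovery_fraction_top30 = mean(planted %in% top30))
  }

  provenance <- list(config_hash = .config_hash(config), seed = config$seed,
                     n_runs = config$n_runs, cap = config$cap)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(tibble::as_tibble(sig),
                     file.path(config$out_dir, "signature.tsv"))
    .write_report(
      c(provenance, list(
        runs = purrr::map(ens, function(r)
          list(seed = r$seed, b = r$b, best_rmse = r$best_rmse,
               selected = r$selected,
               rmse_profile = r$rmse_profile)),
        truth_eval = truth_eval)),
      config$out_dir, "runs.json")
  }
  structure(list(signature = sig, ensemble = ens, truth_eval = truth_eval,
                 provenance = provenance),
            class = "signature_result")
}
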