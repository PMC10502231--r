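#' Construct a clone preset
#'
#' A clone preset bundles the ground-truth parameters of one (simulated)
#' clonal cell population: per-drug 4PL dose-response parameters, a true
#' population doubling time, and mean survival fractions at specific
#' drug/dose combinations (the quantities measured when every clone is
#' treated at the potency of its parental population).
#'
#' @param name Clone label, e.g. `"parental_BxPC3"` or `"B2D9"`.
#' @param drug_params Named list, one entry per drug, each a list with
#'   elements `ic50_true` (concentration, same units as the dose grid),
#'   `hill` (dimensionless, negative for inhibition), `top` and `bottom`
#'   (asymptotic survival fractions).
#' @param pdt_true True population doubling time in hours.
#' @param survival_mean Tibble with columns `drug`, `dose`,
#'   `fraction`: mean survival fraction when treated at `dose`. May be
#'   empty.
#' @return An object of class `clone_preset`.
#' @seealso [builtin_presets()]
#' @export
clone_preset <- function(name, drug_params, pdt_true, survival_mean = NULL) {
  stopifnot(is.character(name), length(name) == 1L, pdt_true > 0)
  for (dp in drug_params) {
    stopifnot(dp$ic50_true > 0, dp$bottom < dp$top)
  }
  if (is.null(survival_mean)) {
    survival_mean <- tibble::tibble(drug = character(), dose = double(),
                                    fraction = double())
  }
  stopifnot(all(survival_mean$fraction >= 0), all(survival_mean$fraction <= 1))
  structure(
    list(name = name, drug_params = drug_params, pdt_true = pdt_true,
         survival_mean = survival_mean),
    class = "clone_preset"
  )
}

#' @export
print.clone_preset <- function(x, ...) {
  cat("<clone_preset> ", x$name, "  (PDT ", x$pdt_true, " h)\n", sep = "")
  for (drug in names(x$drug_params)) {
    dp <- x$drug_params[[drug]]
    cat(sprintf("  %s: ic50 = %.4g, hill = %.2f, top = %.2f, bottom = %.2f\n",
                drug, dp$ic50_true, dp$hill, dp$top, dp$bottom))
  }
  if (nrow(x$survival_mean)) {
    cat("  survival means:\n")
    print(x$survival_mean)
  }
  invisible(x)
}

# Default 4PL shape used where only a potency (or only a survival fraction)
# is known: Hill slope -1.2, full viability untreated, partial-kill plateau
# of 5% (gemcitabine) or 10% (JQ1) residual viability.
.default_shape <- function(drug) {
  list(hill = -1.2, top = 1,
       bottom = if (drug == "JQ1") 0.10 else 0.05)
}

.gem_param <- function(ic50) c(list(ic50_true = ic50), .default_shape("gemcitabine"))
.jq1_param <- function(ic50) c(list(ic50_true = ic50), .default_shape("JQ1"))

# Build a clone whose gemcitabine potency is derived from its survival
# fraction at the parental IC50 dose, so that drug_params and survival_mean
# are mutually consistent.
.clone_from_survival <- function(name, surv_at_parental, parental_ic50_dose,
                                 jq1_ic50, pdt) {
  sh <- .default_shape("gemcitabine")
  gem_ic50 <- fourpl_solve_ic50(surv_at_parental, parental_ic50_dose,
                                top = sh$top, bottom = sh$bottom,
                                hill = sh$hill)
  clone_preset(
    name,
    drug_params = list(gemcitabine = .gem_param(gem_ic50),
                       JQ1 = .jq1_param(jq1_ic50)),
    pdt_true = pdt,
    survival_mean = tibble::tibble(drug = "gemcitabine",
                                   dose = parental_ic50_dose,
                                   fraction = surv_at_parental)
  )
}

#' Built-in clone presets
#'
#' Ground-truth parameter bundles for the parental BxPC3 and Panc-1
#' pancreatic-cancer cell populations and their best-characterized single
#' cell-derived clones. Potencies and doubling times come from published
#' measurements of these lines: gemcitabine IC50 9.6 nmol/L (parental
#' BxPC3) and 43 nmol/L (parental Panc-1); JQ1 IC50s 184.3/48.36/95.63 nM
#' for parental BxPC3/B2D9/B3C10 and 679/471.8/1590 nM for parental
#' Panc-1/P4E2/P4B9; doubling times 31.47/44.27/29.28/34.13/32.82 h for the
#' BxPC3 family and 26.86/29.42/29.91 h for the Panc-1 family. Where a
#' clone's own gemcitabine potency is not published, it is derived from the
#' clone's survival fraction at the parental IC50 dose (0.67 for B2D9, 0.29
#' for B3C10, 0.8 for P4E2, 0.66 for P4B9); B2F8 and B1G3 carry
#' interpolated survival means (0.55, 0.50) and the parental JQ1 potency as
#' placeholders. Unpublished 4PL shape parameters default to Hill slope
#' -1.2, top 1, bottom 0.05 (gemcitabine) / 0.1 (JQ1).
#'
#' @param name Optional preset name; if given, that single preset is
#'   returned and an unknown name is an error.
#' @return A named list of [clone_preset] objects (or a single preset).
#' @examples
#' builtin_presets()[["parental_Panc1"]]$drug_params$gemcitabine$ic50_true
#' builtin_presets("B2D9")$pdt_true
#' @export
builtin_presets <- function(name = NULL) {
  presets <- list(
    parental_BxPC3 = clone_preset(
      "parental_BxPC3",
      drug_params = list(gemcitabine = .gem_param(9.6),
                         JQ1 = .jq1_param(184.3)),
      pdt_true = 31.47,
      survival_mean = tibble::tibble(
        drug = "gemcitabine", dose = 9.6,
        fraction = fourpl(9.6, 1, 0.05, 9.6, -1.2))
    ),
    B2D9  = .clone_from_survival("B2D9",  0.67, 9.6, jq1_ic50 = 48.36,
                                 pdt = 44.27),
    B3C10 = .clone_from_survival("B3C10", 0.29, 9.6, jq1_ic50 = 95.63,
                                 pdt = 29.28),
    B2F8  = .clone_from_survival("B2F8",  0.55, 9.6, jq1_ic50 = 184.3,
                                 pdt = 34.13),
    B1G3  = .clone_from_survival("B1G3",  0.50, 9.6, jq1_ic50 = 184.3,
                                 pdt = 32.82),
    parental_Panc1 = clone_preset(
      "parental_Panc1",
      drug_params = list(gemcitabine = .gem_param(43),
                         JQ1 = .jq1_param(679)),
      pdt_true = 26.86,
      survival_mean = tibble::tibble(
        drug = "gemcitabine", dose = 43,
        fraction = fourpl(43, 1, 0.05, 43, -1.2))
    ),
    P4E2 = .clone_from_survival("P4E2", 0.80, 43, jq1_ic50 = 471.8,
                                pdt = 29.42),
    P4B9 = .clone_from_survival("P4B9", 0.66, 43, jq1_ic50 = 1590,
                                pdt = 29.91)
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    stop("unknown preset: '", name, "'. Available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  presets[[name]]
}

#' Default dose grids
#'
#' The tested concentration series: an 8-point two-fold gemcitabine series
#' spanning 2.5-320 nmol/L and a 7-point five-fold JQ1 series spanning
#' 1.92-30,000 nM.
#'
#' @param drug `"gemcitabine"` or `"JQ1"`.
#' @return Sorted numeric vector of concentrations.
#' @export
default_dose_grid <- function(drug = c("gemcitabine", "JQ1")) {
  drug <- match.arg(drug)
  switch(drug,
         gemcitabine = 2.5 * 2^(0:7),   # 2.5 .. 320 nmol/L
         JQ1         = 1.92 * 5^(0:6))  # 1.92 .. 30,000 nM
}
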