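#' Survival fractions relative to untreated controls
#'
#' Normalizes raw viability signals to the mean untreated-control signal of
#' the same biological replicate (and clone/drug where present): each
#' treated well's fraction is `signal / mean(control signals of its
#' group)`. Fractions may exceed 1; no clipping is applied unless
#' requested, since values above 1 carry information for curve fitting.
#'
#' @param plate Long-format plate tibble as produced by
#'   [simulate_viability_plate()] / [simulate_clone_panel()]: columns
#'   `dose`, `bio_rep`, `treated`, `signal`, optionally `clone` and `drug`.
#' @param clip Clip fractions into \[0, 1\]? Default `FALSE`.
#' @return Tibble of treated wells with a `fraction` column; grouping keys
#'   (`clone`, `drug`, `dose`, `bio_rep`, `tech_rep`) preserved.
#' @examples
#' plate <- simulate_viability_plate(builtin_presets("parental_BxPC3"),
#'                                   "gemcitabine", sim_config(seed = 1))
#' survival_fractions(plate)
#' @export
survival_fractions <- function(plate, clip = FALSE) {
  req <- c("dose", "bio_rep", "treated", "signal")
  if (!all(req %in% names(plate)))
    stop("plate must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  keys <- intersect(c("clone", "drug", "bio_rep"), names(plate))

  ctrl <- plate |>
    dplyr::filter(!.data$treated) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(control_mean = mean(.data$signal), .groups = "drop")
  if (nrow(ctrl) == 0)
    stop("no untreated control wells found", call. = FALSE)
  if (any(ctrl$control_mean <= 0))
    stop("nonpositive control mean in at least one replicate group",
         call. = FALSE)

  out <- plate |>
    dplyr::filter(.data$treated) |>
    dplyr::inner_join(ctrl, by = keys) |>
    dplyr::mutate(fraction = .data$signal / .data$control_mean)
  if (nrow(out) < nrow(dplyr::filter(plate, .data$treated)))
    stop("missing controls for at least one replicate group", call. = FALSE)
  if (clip) out$fraction <- pmin(pmax(out$fraction, 0), 1)
  dplyr::select(out, -"control_mean")
}

# residuals of the 4PL on observed fractions, parameters on transformed
# scale: theta = (top, bottom, log10 ic50, hill)
.fourpl_resid <- function(theta, logd, y) {
  y - (theta[2] + (theta[1] - theta[2]) /
         (1 + 10^((theta[3] - logd) * theta[4])))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of the 4PL model on the log10-dose scale, with a
#' 5-point multi-start over Hill slopes \{-0.5, -1, -2\} and IC50 starts at
#' the geometric mean and the quartiles of the dose grid. The reported fit
#' is the converged start with the lowest residual sum of squares.
#'
#' @param doses Vector of strictly positive concentrations (replicated
#'   doses allowed), or a tibble from [survival_fractions()] (columns
#'   `dose`, `fraction`), in which case `fractions` is ignored.
#' @param fractions Survival fractions matching `doses`.
#' @return An object of class `fourpl_fit`: fields `top`, `bottom`,
#'   `ic50_hat`, `hill`, `rss`, `converged`, `ci95_ic50` (filled by
#'   [bootstrap_ic50_ci()]), `n_points`, plus the data used. `ic50_hat` is
#'   constrained to \[min dose / 10, max dose x 10\].
#' @examples
#' d <- rep(default_dose_grid("gemcitabine"), each = 3)
#' y <- fourpl(d, 1, 0.05, 9.6, -1.2)
#' fit_4pl(d, y)
#' @export
fit_4pl <- function(doses, fractions = NULL) {
  if (is.data.frame(doses)) {
    stopifnot(all(c("dose", "fraction") %in% names(doses)))
    fractions <- doses$fraction
    doses <- doses$dose
  }
  stopifnot(length(doses) == length(fractions),
            all(is.finite(fractions)), all(doses > 0))
  if (length(unique(doses)) < 4)
    stop("at least 4 distinct doses are required for a 4PL fit",
         call. = FALSE)

  logd <- log10(doses)
  y <- fractions
  lo_ic <- min(logd) - 1    # ic50 within [min dose/10, max dose*10]
  hi_ic <- max(logd) + 1
  lower <- c(top = -1, bottom = -1, logic50 = lo_ic, hill = -10)
  upper <- c(top = 3, bottom = 3, logic50 = hi_ic, hill = -0.05)

  if (stats::sd(y) == 0) {
    warning("all fractions identical; 4PL fit did not converge")
    return(structure(
      list(top = y[1], bottom = y[1], ic50_hat = NA_real_, hill = NA_real_,
           rss = 0, converged = FALSE, ci95_ic50 = NULL,
           n_points = length(y), doses = doses, fractions = y),
      class = "fourpl_fit"))
  }

  qs <- stats::quantile(logd, c(0.25, 0.75), names = FALSE)
  starts <- list(
    c(-1, mean(logd)), c(-0.5, mean(logd)), c(-2, mean(logd)),
    c(-1, qs[1]), c(-1, qs[2])
  )
  top0 <- max(y); bot0 <- min(y)

  best <- NULL
  for (s in starts) {
    theta0 <- c(top = top0, bottom = bot0, logic50 = s[2], hill = s[1])
    res <- tryCatch(
      minpack.lm::nls.lm(theta0, lower = lower, upper = upper,
                         fn = .fourpl_resid, logd = logd, y = y,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-12, ptol = 1e-12, maxiter = 200)),
      error = function(e) NULL)
    if (is.null(res)) next
    ok <- res$info %in% 1:3
    rss <- sum(res$fvec^2)
    if (is.null(best) || (ok && !best$ok) || (ok == best$ok && rss < best$rss))
      best <- list(par = res$par, rss = rss, ok = ok)
  }
  if (is.null(best))
    stop("4PL optimization failed from every start", call. = FALSE)

  th <- best$par
  if (th[["top"]] <= th[["bottom"]]) best$ok <- FALSE
  structure(
    list(top = th[["top"]], bottom = th[["bottom"]],
         ic50_hat = 10^th[["logic50"]], hill = th[["hill"]],
         rss = best$rss, converged = best$ok, ci95_ic50 = NULL,
         n_points = length(y), doses = doses, fractions = y,
         start = th),
    class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat("<fourpl_fit> n =", x$n_points,
      if (!x$converged) "(NOT converged)" else "", "\n")
  cat(sprintf("  ic50 = %.4g  hill = %.3f  top = %.3f  bottom = %.3f  rss = %.3g\n",
              x$ic50_hat, x$hill, x$top, x$bottom, x$rss))
  if (!is.null(x$ci95_ic50))
    cat(sprintf("  ic50 CI95: [%.4g, %.4g]\n",
                x$ci95_ic50[1], x$ci95_ic50[2]))
  invisible(x)
}

#' Predict from a 4PL fit
#' @param object A `fourpl_fit`.
#' @param newdata Numeric vector of doses (default: the fitted doses).
#' @param ... Unused.
#' @export
predict.fourpl_fit <- function(object, newdata = NULL, ...) {
  d <- newdata %||% object$doses
  fourpl(d, object$top, object$bottom, object$ic50_hat, object$hill)
}

# single warm-started refit used by the bootstrap
.refit_4pl <- function(logd, y, theta0, lower, upper) {
  res <- tryCatch(
    minpack.lm::nls.lm(theta0, lower = lower, upper = upper,
                       fn = .fourpl_resid, logd = logd, y = y,
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-10, ptol = 1e-10, maxiter = 100)),
    error = function(e) NULL)
  if (is.null(res) || !(res$info %in% 1:3)) return(NA_real_)
  10^res$par[["logic50"]]
}

#' Bootstrap confidence interval for the IC50
#'
#' Case (pairs) bootstrap: resample (dose, fraction) points with
#' replacement, refit the 4PL warm-started at the full-data estimate, and
#' take the percentile interval of the converged IC50 replicates.
#'
#' @param doses,fractions As in [fit_4pl()]; a `fourpl_fit` may be passed
#'   as `doses`, in which case its stored data are reused.
#' @param B Number of bootstrap replicates (>= 100; default 1000).
#' @param seed Integer seed; the interval is deterministic given the seed.
#' @param level Confidence level (default 0.95).
#' @return A `fourpl_fit` whose `ci95_ic50` is set to `c(lo, hi)`, with
#'   attribute `"n_boot_ok"` giving the number of usable replicates.
#' @export
bootstrap_ic50_ci <- function(doses, fractions = NULL, B = 1000L, seed = 1L,
                              level = 0.95) {
  if (B < 100) stop("B must be at least 100", call. = FALSE)
  fit <- if (inherits(doses, "fourpl_fit")) doses else fit_4pl(doses, fractions)
  if (!fit$converged)
    stop("cannot bootstrap a non-converged fit", call. = FALSE)

  logd <- log10(fit$doses)
  y <- fit$fractions
  n <- length(y)
  lower <- c(top = -1, bottom = -1, logic50 = min(logd) - 1, hill = -10)
  upper <- c(top = 3, bottom = 3, logic50 = max(logd) + 1, hill = -0.05)
  theta0 <- c(top = fit$top, bottom = fit$bottom,
              logic50 = log10(fit$ic50_hat), hill = fit$hill)

  reps <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(logd[idx])) < 4) return(NA_real_)
      .refit_4pl(logd[idx], y[idx], theta0, lower, upper)
    }, numeric(1))
  })
  ok <- reps[is.finite(reps)]
  if (length(ok) < B / 2)
    warning("fewer than half of the bootstrap refits converged")
  a <- (1 - level) / 2
  ci <- stats::quantile(ok, c(a, 1 - a), names = FALSE, type = 7)
  fit$ci95_ic50 <- ci
  attr(fit$ci95_ic50, "n_boot_ok") <- length(ok)
  fit
}

#' Dose close to maximal inhibition (ICmax) from a fitted curve
#'
#' Operationalizes "a concentration close to the maximal inhibitory
#' concentration" as the smallest tested dose at which the fitted curve
#' achieves at least `threshold` (default 95%) of its maximal inhibition
#' `top - bottom`. If no tested dose qualifies, the largest tested dose is
#' returned with `reached = FALSE`.
#'
#' @param fit A converged `fourpl_fit`.
#' @param dose_grid Tested concentrations to search over.
#' @param threshold Fraction of maximal inhibition required (default 0.95).
#' @return One-row tibble: `icmax` (dose), `inhibition` (achieved fraction
#'   of maximal inhibition at that dose), `reached` (logical flag).
#' @export
icmax_from_fit <- function(fit, dose_grid, threshold = 0.95) {
  stopifnot(inherits(fit, "fourpl_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (length(dose_grid) == 0) stop("empty dose grid", call. = FALSE)
  dose_grid <- sort(dose_grid)
  f <- predict(fit, dose_grid)
  inhib <- (fit$top - f) / (fit$top - fit$bottom)
  hit <- which(inhib >= threshold)
  if (length(hit)) {
    tibble::tibble(icmax = dose_grid[hit[1]], inhibition = inhib[hit[1]],
                   reached = TRUE)
  } else {
    k <- length(dose_grid)
    tibble::tibble(icmax = dose_grid[k], inhibition = inhib[k],
                   reached = FALSE)
  }
}

#' Per-dose Welch comparison of two clone panels
#'
#' For every dose shared by the two plates, compares survival fractions
#' with an unequal-variance two-sample t-test (Welch). No multiplicity
#' adjustment is applied, matching common per-dose reporting of
#' dose-response differences. Doses at which both groups are numerically
#' constant are flagged as degenerate: p = 1 when the means agree, p = 0
#' when they differ.
#'
#' @param panelA,panelB Plate tibbles (raw signals; fractions are computed
#'   internally) or tibbles already carrying a `fraction` column.
#' @return Tibble with one row per shared dose: `dose`, `mean_a`, `mean_b`,
#'   `statistic`, `p_value`, `degenerate`.
#' @export
per_dose_comparison <- function(panelA, panelB) {
  frac <- function(x) if ("fraction" %in% names(x)) x else survival_fractions(x)
  a <- frac(panelA); b <- frac(panelB)
  shared <- intersect(unique(a$dose), unique(b$dose))
  if (length(shared) == 0)
    stop("panels share no doses", call. = FALSE)

  purrr::map_dfr(sort(shared), function(d) {
    xa <- a$fraction[a$dose == d]
    xb <- b$fraction[b$dose == d]
    if (length(xa) < 2 || length(xb) < 2)
      stop("need >= 2 replicates per group at every shared dose",
           call. = FALSE)
    degen <- stats::sd(xa) < 1e-12 && stats::sd(xb) < 1e-12
    if (degen) {
      same <- abs(mean(xa) - mean(xb)) < 1e-12
      tibble::tibble(dose = d, mean_a = mean(xa), mean_b = mean(xb),
                     statistic = if (same) 0 else Inf,
                     p_value = if (same) 1 else 0, degenerate = TRUE)
    } else {
      tt <- stats::t.test(xa, xb, var.equal = FALSE)
      tibble::tibble(dose = d, mean_a = mean(xa), mean_b = mean(xb),
                     statistic = unname(tt$statistic),
                     p_value = tt$p.value, degenerate = FALSE)
    }
  })
}
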