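preset_bx <- builtin_presets("parental_BxPC3")

make_clean_curve <- function(ic50 = 43, hill = -1.2, top = 1, bottom = 0.05,
                             doses = rep(default_dose_grid("gemcitabine"),
                                         each = 3)) {
  list(doses = doses, fractions = fourpl(doses, top, bottom, ic50, hill),
       truth = c(top = top, bottom = bottom, ic50 = ic50, hill = hill))
}

test_that("survival fractions normalize to per-replicate control means", {
  plate <- tibble::tibble(
    clone = "toy", drug = "d",
    dose = c(0, 0, 10, 10, 0, 0, 10, 10),
    bio_rep = c(1, 1, 1, 1, 2, 2, 2, 2),
    tech_rep = rep(1:2, 4),
    treated = dose > 0,
    signal = c(100, 100, 100, 0, 200, 200, 100, 300))
  fr <- survival_fractions(plate)
  # rep 1 control mean 100 -> fractions 1, 0; rep 2 control mean 200 -> 0.5, 1.5
  expect_equal(fr$fraction[fr$bio_rep == 1], c(1, 0))
  expect_equal(fr$fraction[fr$bio_rep == 2], c(0.5, 1.5))
  expect_equal(survival_fractions(plate, clip = TRUE)$fraction,
               pmin(fr$fraction, 1))

  # invariant to rescaling all raw signals
  plate2 <- dplyr::mutate(plate, signal = signal * 37.5)
  expect_equal(survival_fractions(plate2)$fraction, fr$fraction)
})

test_that("missing or nonpositive controls are rejected", {
  plate <- tibble::tibble(
    dose = c(10, 10), bio_rep = c(1, 1), treated = c(TRUE, TRUE),
    signal = c(1, 2))
  expect_error(survival_fractions(plate), "control")
  plate0 <- tibble::tibble(
    dose = c(0, 10), bio_rep = c(1, 1), treated = c(FALSE, TRUE),
    signal = c(0, 2))
  expect_error(survival_fractions(plate0), "nonpositive")
})

test_that("B2D9 panel at the parental IC50 recovers the 0.67 survival rate", {
  cfg <- sim_config(seed = 7)
  panel <- simulate_clone_panel(builtin_presets("B2D9"), "gemcitabine", 9.6,
                                cfg)
  fr <- survival_fractions(panel)
  expect_equal(nrow(fr), 9)
  expect_lt(abs(mean(fr$fraction) - 0.67), 0.05)
})

test_that("noise-free 4PL data are recovered to 1e-6 in all parameters", {
  for (ic50 in c(9.6, 43, 679)) {
    cc <- make_clean_curve(ic50 = ic50,
                           doses = rep(if (ic50 > 300)
                             default_dose_grid("JQ1") else
                               default_dose_grid("gemcitabine"), each = 3))
    fit <- fit_4pl(cc$doses, cc$fractions)
    expect_true(fit$converged)
    expect_equal(fit$ic50_hat, ic50, tolerance = 1e-6)
    expect_equal(fit$hill, -1.2, tolerance = 1e-6)
    expect_equal(fit$top, 1, tolerance = 1e-6)
    expect_equal(fit$bottom, 0.05, tolerance = 1e-6)
  }
})

test_that("noisy parental BxPC3 plates recover the 9.6 nmol/L potency", {
  fits <- vapply(1:5, function(s) {
    plate <- simulate_viability_plate(preset_bx, "gemcitabine",
                                      sim_config(seed = s))
    fr <- survival_fractions(plate)
    fit_4pl(fr$dose, fr$fraction)$ic50_hat
  }, numeric(1))
  expect_lt(abs(median(fits) - 9.6) / 9.6, 0.15)
})

test_that("fitted rss beats a brute-force parameter grid around the truth", {
  cc <- make_clean_curve(ic50 = 43)
  set.seed(42)
  y <- cc$fractions + rnorm(length(cc$fractions), 0, 0.03)
  fit <- fit_4pl(cc$doses, y)
  grid <- expand.grid(
    top = seq(0.9, 1.1, length.out = 20),
    bottom = seq(-0.05, 0.15, length.out = 20),
    logic50 = seq(log10(43) - 0.3, log10(43) + 0.3, length.out = 20),
    hill = seq(-2, -0.6, length.out = 20))
  logd <- log10(cc$doses)
  rss_grid <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    pred <- g$bottom + (g$top - g$bottom) /
      (1 + 10^((g$logic50 - logd) * g$hill))
    sum((y - pred)^2)
  }, numeric(1))
  expect_lte(fit$rss, min(rss_grid) + 1e-10)
})

test_that("4PL fit is scale-equivariant in dose", {
  cc <- make_clean_curve(ic50 = 43)
  fit1 <- fit_4pl(cc$doses, cc$fractions)
  fit2 <- fit_4pl(cc$doses * 1000, cc$fractions)   # nmol/L -> pmol/L
  expect_equal(fit2$ic50_hat / fit1$ic50_hat, 1000, tolerance = 1e-6)
  expect_equal(fit2$hill, fit1$hill, tolerance = 1e-6)
})

test_that("degenerate 4PL inputs fail honestly", {
  expect_error(fit_4pl(c(1, 2, 4), c(1, 0.5, 0.2)), "4 distinct doses")
  expect_warning(fit <- fit_4pl(rep(c(1, 2, 4, 8), 2), rep(0.5, 8)),
                 "identical")
  expect_false(fit$converged)
})

test_that("bootstrap CI behaves: degeneracy, coverage of the estimate, B guard", {
  cc <- make_clean_curve(ic50 = 9.6,
                         doses = rep(default_dose_grid("gemcitabine"),
                                     each = 3))
  fit <- bootstrap_ic50_ci(cc$doses, cc$fractions, B = 100, seed = 1)
  # noise-free: every resample refits the same exact curve
  expect_lt(diff(fit$ci95_ic50), 1e-6 * fit$ic50_hat)

  plate <- simulate_viability_plate(preset_bx, "gemcitabine",
                                    sim_config(seed = 3))
  fr <- survival_fractions(plate)
  f2 <- bootstrap_ic50_ci(fr$dose, fr$fraction, B = 200, seed = 5)
  expect_true(f2$ci95_ic50[1] <= f2$ic50_hat &&
                f2$ic50_hat <= f2$ci95_ic50[2])
  f3 <- bootstrap_ic50_ci(fr$dose, fr$fraction, B = 200, seed = 5)
  expect_identical(f2$ci95_ic50, f3$ci95_ic50)

  expect_error(bootstrap_ic50_ci(fr$dose, fr$fraction, B = 50), "at least 100")
})

test_that("bootstrap CI width shrinks with replication", {
  widths <- vapply(c(1, 3, 9), function(reps) {
    mean(vapply(1:3, function(s) {
      cfg <- sim_config(seed = s, n_tech_reps = reps, n_bio_reps = 3)
      fr <- survival_fractions(
        simulate_viability_plate(preset_bx, "gemcitabine", cfg))
      f <- bootstrap_ic50_ci(fr$dose, fr$fraction, B = 150, seed = s)
      diff(f$ci95_ic50)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))   # monotone over 3 -> 9 -> 27 wells
})

test_that("bootstrap CI coverage is near nominal at default noise", {
  covered <- vapply(1:100, function(s) {
    fr <- survival_fractions(
      simulate_viability_plate(preset_bx, "gemcitabine", sim_config(seed = s)))
    f <- bootstrap_ic50_ci(fr$dose, fr$fraction, B = 199, seed = s)
    f$ci95_ic50[1] <= 9.6 && 9.6 <= f$ci95_ic50[2]
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("ICmax is the smallest dose reaching 95% of maximal inhibition", {
  grid <- default_dose_grid("gemcitabine")
  # steep curve saturates mid-grid
  steep <- fit_4pl(rep(grid, 3), rep(fourpl(grid, 1, 0.05, 10, -4), 3))
  im <- icmax_from_fit(steep, grid)
  expect_true(im$reached)
  expect_lt(im$icmax, max(grid))
  expect_equal(im$icmax,
               grid[which(fourpl(grid, steep$top, steep$bottom,
                                 steep$ic50_hat, steep$hill) <=
                            steep$top - 0.95 * (steep$top - steep$bottom))[1]])

  # shallow curve never gets there: fallback to the max dose, flagged
  shallow <- fit_4pl(rep(grid, 3), rep(fourpl(grid, 1, 0.05, 300, -0.8), 3))
  im2 <- icmax_from_fit(shallow, grid)
  expect_false(im2$reached)
  expect_equal(im2$icmax, max(grid))

  # threshold 1.0 demands full maximal inhibition: fallback on any finite grid
  im3 <- icmax_from_fit(steep, grid, threshold = 1.0)
  expect_false(im3$reached)
  expect_error(icmax_from_fit(steep, numeric(0)), "empty")
})

test_that("per-dose Welch comparison flags degeneracy and finds real differences", {
  mk <- function(vals, dose = 10) tibble::tibble(
    dose = dose, bio_rep = seq_along(vals), fraction = vals)
  same <- per_dose_comparison(mk(c(0.5, 0.6, 0.7)), mk(c(0.6, 0.6, 0.6)))
  expect_equal(same$p_value, 1, tolerance = 1e-12)  # equal means -> t = 0

  degen <- per_dose_comparison(mk(c(0.5, 0.5)), mk(c(0.7, 0.7)))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 0)

  expect_error(per_dose_comparison(mk(c(0.5, 0.6), dose = 1),
                                   mk(c(0.5, 0.6), dose = 2)), "share")

  # resistant vs sensitive clones separate at intermediate doses
  cfgA <- sim_config(seed = 5)
  pa <- simulate_viability_plate(builtin_presets("B2D9"), "gemcitabine", cfgA)
  pb <- simulate_viability_plate(builtin_presets("B3C10"), "gemcitabine",
                                 sim_config(seed = 6))
  cmp <- per_dose_comparison(pa, pb)
  mid <- cmp[cmp$dose %in% c(5, 10, 20, 40, 80), ]
  expect_true(all(mid$p_value < 0.05))
})
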