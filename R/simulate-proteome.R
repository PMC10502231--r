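#' Proteome matrix container
#'
#' Bundles a proteins-by-samples intensity matrix (MaxLFQ-like linear
#' intensities unless `log2 = TRUE`), the per-sample continuous response
#' (survival fraction under treatment), and — for simulated data — the
#' planted ground truth.
#'
#' @param intensities Numeric matrix, proteins in rows (rownames = protein
#'   ids), samples in columns (colnames = sample ids). `NA` marks missing
#'   quantifications.
#' @param response Numeric vector of per-sample survival fractions, one per
#'   column, in the column order (names optional but checked if present).
#' @param log2 Logical: are the stored intensities already
#'   log2-transformed?
#' @param truth Optional list describing simulated ground truth.
#' @return An object of class `proteome_matrix`.
#' @export
proteome_matrix <- function(intensities, response, log2 = FALSE,
                            truth = NULL) {
  stopifnot(is.matrix(intensities), !is.null(rownames(intensities)),
            !is.null(colnames(intensities)))
  if (anyDuplicated(rownames(intensities)))
    stop("duplicate protein ids", call. = FALSE)
  if (length(response) != ncol(intensities))
    stop("response length must equal the number of samples", call. = FALSE)
  if (!is.null(names(response)) &&
      !identical(names(response), colnames(intensities)))
    stop("response names do not match sample ids", call. = FALSE)
  names(response) <- colnames(intensities)
  structure(list(intensities = intensities, response = response,
                 log2 = isTRUE(log2), truth = truth),
            class = "proteome_matrix")
}

#' @export
print.proteome_matrix <- function(x, ...) {
  cat("<proteome_matrix> ", nrow(x$intensities), " proteins x ",
      ncol(x$intensities), " samples (",
      if (x$log2) "log2" else "linear", " scale, ",
      round(100 * mean(is.na(x$intensities)), 1), "% missing)\n", sep = "")
  if (!is.null(x$truth))
    cat("  simulated: ", nrow(x$truth$planted), " planted proteins, effect ",
        x$truth$effect_size, "\n", sep = "")
  invisible(x)
}

#' @export
dim.proteome_matrix <- function(x) dim(x$intensities)

#' Simulate a DIA-style protein intensity matrix with planted signal
#'
#' Generates log-normal protein abundances for `n_proteins` proteins over
#' `n_samples` clone samples, a continuous per-sample response (survival
#' fraction at the parental IC50, drawn uniformly from
#' `config$response_range`), and plants `n_planted` response-associated
#' proteins: half with abundance rising with response (markers of
#' resistance), half falling. On the log2 scale
#' \deqn{x_{ij} = \mu_i + s_i \,\beta\, r_j + \varepsilon_{ij}}
#' with per-protein baseline \eqn{\mu_i \sim N} (log-normal abundance),
#' planted sign \eqn{s_i \in \{+1, -1, 0\}}, effect size \eqn{\beta} =
#' `config$effect_size`, response \eqn{r_j}, and noise SD
#' `config$proteome_noise_sd`. Entries are then censored
#' abundance-dependently (logistic in log2 intensity, low abundance
#' preferentially missing) so that the expected overall missing fraction is
#' `config$missing_rate`.
#'
#' @param config A [sim_config]; uses `n_samples`, `n_proteins`,
#'   `n_planted`, `effect_size`, `missing_rate`, `response_range`,
#'   `baseline_mean_log2`, `baseline_sd_log2`, `proteome_noise_sd`, `seed`.
#' @param seed Optional seed overriding `config$seed`.
#' @return A [proteome_matrix] with linear-scale intensities and a `truth`
#'   list (`planted` tibble with `protein_id` and `sign`, plus the
#'   generating parameters).
#' @examples
#' pm <- simulate_proteome(sim_config(n_proteins = 100, n_planted = 10,
#'                                    seed = 11))
#' pm
#' @export
simulate_proteome <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples < 6)
    stop("at least 6 samples are required", call. = FALSE)
  if (diff(config$response_range) <= 0)
    stop("degenerate response range: response would have zero variance",
         call. = FALSE)

  p <- config$n_proteins
  n <- config$n_samples
  withr::with_seed(seed %||% config$seed, {
    protein_ids <- sprintf("PROT%04d", seq_len(p))
    sample_ids <- sprintf("clone_%02d", seq_len(n))
    response <- stats::runif(n, config$response_range[1],
                             config$response_range[2])
    names(response) <- sample_ids

    baseline <- stats::rnorm(p, config$baseline_mean_log2,
                             config$baseline_sd_log2)
    sign_vec <- numeric(p)
    planted_idx <- sample.int(p, config$n_planted)
    if (config$n_planted > 0) {
      n_pos <- ceiling(config$n_planted / 2)
      sign_vec[planted_idx] <- rep(c(1, -1),
                                   c(n_pos, config$n_planted - n_pos))
    }

    x <- outer(baseline, rep(1, n)) +
      outer(sign_vec * config$effect_size, response) +
      matrix(stats::rnorm(p * n, 0, config$proteome_noise_sd), p, n)
    dimnames(x) <- list(protein_ids, sample_ids)

    if (config$missing_rate > 0) {
      # logistic left-censoring: P(missing | x) = plogis((tau - x)/scale);
      # tau calibrated so the expected overall missing fraction hits target
      scale <- 1
      f <- function(tau) mean(stats::plogis((tau - x) / scale)) -
        config$missing_rate
      tau <- stats::uniroot(f, lower = min(x) - 50, upper = max(x) + 50)$root
      pmiss <- stats::plogis((tau - x) / scale)
      x[stats::runif(p * n) < pmiss] <- NA_real_
    }

    truth <- list(
      planted = tibble::tibble(
        protein_id = protein_ids[planted_idx],
        sign = sign_vec[planted_idx]),
      effect_size = config$effect_size,
      seed = seed %||% config$seed,
      response_range = config$response_range
    )
    proteome_matrix(2^x, response, log2 = FALSE, truth = truth)
  })
}
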