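#' Filter, impute and transform a proteome matrix
#'
#' Drops proteins quantified in fewer than `min_presence` of the samples,
#' imputes each remaining missing entry with half the protein's minimum
#' observed intensity (the usual left-censoring convention for
#' data-independent acquisition data), and optionally log2-transforms.
#'
#' @param pm A [proteome_matrix].
#' @param min_presence Minimum fraction of samples a protein must be
#'   quantified in (default 0.7).
#' @param log2_transform Log2-transform intensities after imputation
#'   (default `TRUE`; a no-op if the matrix is already on the log2 scale).
#' @return A [proteome_matrix] with no missing values.
#' @export
preprocess_proteome <- function(pm, min_presence = 0.7,
                                log2_transform = TRUE) {
  stopifnot(inherits(pm, "proteome_matrix"),
            min_presence > 0, min_presence <= 1)
  x <- pm$intensities
  presence <- rowMeans(!is.na(x))
  x <- x[presence >= min_presence, , drop = FALSE]
  if (nrow(x) == 0)
    stop("no proteins pass the presence filter", call. = FALSE)

  miss <- is.na(x)
  if (any(miss)) {
    halfmin <- apply(x, 1, min, na.rm = TRUE) / 2
    x[miss] <- halfmin[row(x)[miss]]
  }
  if (log2_transform && !pm$log2) {
    if (any(x <= 0)) stop("nonpositive intensities cannot be log2-transformed",
                          call. = FALSE)
    x <- log2(x)
    lg <- TRUE
  } else {
    lg <- pm$log2
  }
  proteome_matrix(x, pm$response, log2 = lg, truth = pm$truth)
}
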