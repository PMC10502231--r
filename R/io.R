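#' Read and write the pipeline's tabular formats
#'
#' All tables are tab-separated with a header row. A proteome is stored as
#' a proteins-in-rows matrix TSV whose first column is the protein id, plus
#' a two-column sample/response TSV; simulated ground truth travels in a
#' JSON sidecar.
#'
#' @param x Object to write.
#' @param path,matrix_path,response_path,truth_path File paths.
#' @return Readers return tibbles / [proteome_matrix] objects; writers
#'   return the path(s) invisibly.
#' @name clonesig-io
NULL

#' @rdname clonesig-io
#' @export
write_plate_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname clonesig-io
#' @export
read_plate_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname clonesig-io
#' @export
write_proteome_tsv <- function(x, matrix_path, response_path,
                               truth_path = NULL) {
  stopifnot(inherits(x, "proteome_matrix"))
  mat <- tibble::as_tibble(x$intensities, rownames = "protein_id")
  readr::write_tsv(mat, matrix_path)
  readr::write_tsv(
    tibble::tibble(sample_id = names(x$response), response = x$response),
    response_path)
  if (!is.null(truth_path) && !is.null(x$truth)) {
    jsonlite::write_json(
      list(planted = x$truth$planted, effect_size = x$truth$effect_size,
           seed = x$truth$seed, log2 = x$log2),
      truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(matrix_path, response_path))
}

#' @rdname clonesig-io
#' @export
read_proteome_tsv <- function(matrix_path, response_path,
                              truth_path = NULL) {
  for (p in c(matrix_path, response_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  mat <- readr::read_tsv(matrix_path, show_col_types = FALSE)
  ids <- mat[[1]]
  m <- as.matrix(mat[, -1])
  rownames(m) <- ids
  resp <- readr::read_tsv(response_path, show_col_types = FALSE)
  stopifnot(all(c("sample_id", "response") %in% names(resp)))
  resp <- resp[match(colnames(m), resp$sample_id), ]
  if (any(is.na(resp$response)))
    stop("response file does not cover all matrix samples", call. = FALSE)
  truth <- NULL
  lg <- FALSE
  if (!is.null(truth_path) && file.exists(truth_path)) {
    j <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    truth <- list(planted = tibble::as_tibble(j$planted),
                  effect_size = j$effect_size, seed = j$seed)
    lg <- isTRUE(j$log2)
  }
  proteome_matrix(m, stats::setNames(resp$response, resp$sample_id),
                  log2 = lg, truth = truth)
}
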