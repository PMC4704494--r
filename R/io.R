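#' Write a screen design or well feature table as TSV
#' @param x data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_screen_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by \code{write_screen_tsv}
#' @param path input path.
#' @return data.frame.
#' @export
read_screen_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write ground truth (or any result list) as JSON
#' @param x list; arrays are flattened with their dimensions recorded.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, force = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Write interaction coefficients as long-format TSV
#'
#' Columns: compound, line, feature, replicate, pi.
#' @param result an \code{interaction_result}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_interactions_tsv <- function(result, path) {
  stopifnot(inherits(result, "interaction_result"))
  long <- expand.grid(compound = result$compounds, line = result$lines,
                      feature = result$features,
                      replicate = seq_len(result$n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$pi <- as.vector(result$pi)
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
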