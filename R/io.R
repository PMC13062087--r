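## Plain-text readers/writers: one-sample-per-row TSV traces with a JSON
## sidecar ({fs, units, t0}), trial tables as TSV, result records as JSON.

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Write a continuous signal as TSV plus JSON sidecar
#'
#' @param x a \code{cont_signal}.
#' @param path TSV path (sidecar written alongside with .json extension).
#' @param extra optional named list merged into the sidecar.
#' @return invisibly, the path.
#' @export
write_signal_tsv <- function(x, path, extra = NULL) {
  stopifnot(inherits(x, "cont_signal"))
  utils::write.table(data.frame(value = x$samples), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- c(list(fs = x$fs, units = x$units, t0 = x$t0), extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a continuous signal from TSV plus JSON sidecar
#'
#' @param path TSV path.
#' @return a \code{cont_signal}.
#' @export
read_signal_tsv <- function(path) {
  v <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  cont_signal(v[[1]], fs = meta$fs, units = meta$units, t0 = meta$t0)
}

#' Write a trial table as TSV
#' @param trials trial data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_trials_tsv <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial table from TSV
#' @param path TSV path.
#' @return data.frame.
#' @export
read_trials_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
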