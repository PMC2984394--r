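format_sig12 <- function(x) {
  if (is.numeric(x)) formatC(x, digits = 12, format = "g") else as.character(x)
}

metadata_header <- function(x, seed = NULL) {
  p <- attr(x, "params")
  lines <- c(paste0("# fihcomp ",
                    as.character(utils::packageVersion("fihcomp"))),
             if (!is.null(attr(x, "model")))
               paste0("# model: ", attr(x, "model")),
             if (!is.null(p))
               paste0("# params: ",
                      paste(names(unclass(p)), vapply(unclass(p), format, ""),
                            sep = "=", collapse = " ")),
             if (!is.null(seed)) paste0("# seed: ", seed))
  lines
}

#' Export simulation objects as annotated CSV
#'
#' Writes trajectories, response curves, memory maps or census tables as
#' CSV with `#`-prefixed metadata header lines (package version, model tag,
#' parameter set, optional seed) so that every output records how to
#' reproduce it. Numeric values carry 12 significant digits and round-trip
#' through [read_export_csv()].
#'
#' @param x a `"fih_trajectory"`, `"fih_response"`, `"fih_memory_map"` or
#'   plain data frame.
#' @param path output path.
#' @param seed optional seed to record in the header.
#' @return `path`, invisibly.
#' @export
export_csv <- function(x, path, seed = NULL) {
  header <- metadata_header(x, seed)
  if (inherits(x, "fih_memory_map")) {
    df <- as.data.frame(unclass(x))
    names(df) <- paste0("duration_", colnames(x))
    df <- cbind(severity = rownames(x), df)
  } else {
    df <- as.data.frame(x)
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(df) == 0L) {
    writeLines(paste(names(df), collapse = ","), con)
    return(invisible(path))
  }
  out <- as.data.frame(lapply(df, format_sig12), stringsAsFactors = FALSE)
  utils::write.table(out, con, sep = ",", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read back a CSV written by [export_csv()]
#'
#' @param path file path.
#' @return Data frame of the numeric payload (metadata lines skipped).
#' @export
read_export_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
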