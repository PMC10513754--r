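#' Read and write plain-text grids
#'
#' Whitespace-delimited numeric grids (one matrix row per line, `NA` for
#' no-data), the portable raster format used throughout the package for
#' LAI, vegetation-index and yield maps.
#'
#' @param path File path.
#' @return `read_grid()` returns a numeric matrix.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("grid file not found: ", path)
  as.matrix(utils::read.table(path, header = FALSE,
                              colClasses = "numeric"))
}

#' @rdname read_grid
#' @param x Numeric matrix to write.
#' @export
write_grid <- function(x, path) {
  stopifnot(is.matrix(x))
  utils::write.table(format(x, trim = TRUE, digits = 10), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
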