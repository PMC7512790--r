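# Readers and writers for images, label maps, membership matrices and tables.

.file_ext <- function(path) tolower(tools::file_ext(path))

#' Read a grayscale image
#'
#' Supported formats, selected by extension: PNG (intensities scaled to
#' [0, 1] as stored; multi-channel images are collapsed by averaging the
#' channels), TIFF (raw sample values as floats, no rescaling, any bit
#' depth), and delimited numeric text grids (whitespace- or, for `.csv`,
#' comma-separated) which round-trip losslessly with [write_image()].
#'
#' @param path File path.
#' @return Numeric matrix of intensities.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image: '%s' does not exist", path), call. = FALSE)
  ext <- .file_ext(path)
  a <- switch(
    ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    {
      m <- tryCatch(
        as.matrix(read.table(path, header = FALSE,
                             sep = if (ext == "csv") "," else "")),
        error = function(e) stop(sprintf(
          "malformed file '%s': expected a delimited numeric grid (%s)",
          path, conditionMessage(e)), call. = FALSE)
      )
      if (!is.numeric(m)) stop(sprintf("malformed file '%s': expected a delimited numeric grid", path), call. = FALSE)
      dimnames(m) <- NULL
      return(m)
    }
  )
  if (length(dim(a)) == 3) a <- apply(a, c(1, 2), mean)
  storage.mode(a) <- "double"
  a
}

#' Write a grayscale image
#'
#' Delimited text (default) preserves intensities exactly; PNG rescales to
#' [0, 1] over the image's own range (for visual inspection only).
#'
#' @param img Numeric matrix.
#' @param path Destination; `.png` writes PNG, anything else a whitespace-
#'   delimited grid.
#' @export
write_image <- function(img, path) {
  if (.file_ext(path) == "png") {
    r <- range(img)
    scaled <- if (diff(r) > 0) (img - r[1]) / diff(r) else img * 0
    png::writePNG(scaled, path)
  } else {
    write.table(matrix(formatC(img, digits = 17, format = "g"), nrow(img)),
                path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a label map
#'
#' `.png` paths produce a gray-level map with one evenly spaced gray level
#' per class; any other path writes an integer-delimited grid that
#' round-trips exactly with [read_labels()].
#'
#' @param labels Integer label matrix.
#' @param path Destination path.
#' @export
write_labels <- function(labels, path) {
  if (.file_ext(path) == "png") {
    k <- max(labels)
    png::writePNG(labels / max(1, k), path)
  } else {
    write.table(labels, path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a label map from a delimited file
#'
#' @param path File path of an integer-delimited grid.
#' @return Integer label matrix.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read labels: '%s' does not exist", path), call. = FALSE)
  m <- as.matrix(read.table(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Write a membership matrix
#'
#' Plain-text format: a one-line header `n c` followed by the n x c matrix,
#' full double precision.
#'
#' @param U Membership matrix.
#' @param path Destination path.
#' @export
write_memberships <- function(U, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(U), ncol(U)), con)
  write.table(matrix(formatC(U, digits = 17, format = "g"), nrow(U)),
              con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a membership matrix written by [write_memberships()]
#'
#' @param path File path.
#' @return n x c numeric matrix.
#' @export
read_memberships <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read memberships: '%s' does not exist", path), call. = FALSE)
  header <- tryCatch(scan(path, what = integer(), n = 2, quiet = TRUE),
                     error = function(e) integer(0))
  if (length(header) != 2) {
    stop(sprintf("malformed file '%s': expected a one-line 'n c' header", path), call. = FALSE)
  }
  vals <- scan(path, what = double(), skip = 1, quiet = TRUE)
  if (length(vals) != header[1] * header[2]) {
    stop(sprintf("malformed file '%s': expected %d x %d values", path, header[1], header[2]),
         call. = FALSE)
  }
  matrix(vals, nrow = header[1], ncol = header[2], byrow = TRUE)
}

#' Write an accuracy table as CSV
#'
#' @param table Data frame (e.g. from [run_experiment()]).
#' @param path Destination `.csv` path.
#' @export
write_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
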