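## Field serialization.
##
## Two on-disk representations of a VectorField2D:
##  * TIFF: two 32-bit float pages (x then y component). The tiff codec
##    stores values in [0, 1], so each page is affine-rescaled and the
##    scale, offset, units and pixel spacing are recorded in a JSON
##    sidecar (<path>.json); precision is that of float32 (~1e-7
##    relative).
##  * CSV: columns x_px, y_px, comp_x, comp_y (0-based pixel indices,
##    row-major, origin top-left; physical position = index * spacing),
##    with units and spacing in '#'-prefixed header lines. Values are
##    written at full double precision, so CSV round trips are exact.

.sidecar <- function(path) paste0(path, ".json")

#' Write a vector field to disk
#'
#' @param field a [VectorField2D-class].
#' @param path output path; extension .tif/.tiff selects TIFF (plus a
#'   .json metadata sidecar), .csv selects CSV.
#' @return the path, invisibly.
#' @export
writeField <- function(field, path) {
  validObject(field)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    sc <- function(m) {
      lo <- min(m); hi <- max(m)
      s <- if (hi > lo) hi - lo else 1
      list(data = (m - lo) / s, offset = lo, scale = s)
    }
    x <- sc(field@x); y <- sc(field@y)
    tiff::writeTIFF(list(x$data, y$data), path, bits.per.sample = 32L,
                    compression = "none", reduce = FALSE)
    jsonlite::write_json(
      list(units = field@units, spacing_um = field@spacing,
           dims = dim(field@x),
           offset = c(x$offset, y$offset), scale = c(x$scale, y$scale),
           pixel_convention = "0-based, row-major, origin top-left"),
      .sidecar(path), auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    dims <- dim(field@x)
    idx <- gridPoints(dims)
    df <- data.frame(x_px = idx[, 2] - 1L, y_px = idx[, 1] - 1L,
                     comp_x = sprintf("%.17g", as.vector(field@x)),
                     comp_y = sprintf("%.17g", as.vector(field@y)))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      paste0("# units=", field@units),
      paste0("# spacing_um=", sprintf("%.17g", field@spacing)),
      paste0("# dims=", dims[1], "x", dims[2]),
      "# pixel convention: 0-based, row-major, origin top-left"), con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  } else {
    stop("unsupported field format: .", ext)
  }
  invisible(path)
}

#' Read a vector field from disk
#'
#' @param path a .tif/.tiff (with its .json sidecar) or .csv file written
#'   by [writeField()].
#' @return a [VectorField2D-class].
#' @export
readField <- function(path) {
  if (!file.exists(path)) stop("field file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!file.exists(.sidecar(path)))
      stop("missing metadata sidecar for field '", path,
           "': cannot determine spacing and units")
    meta <- jsonlite::read_json(.sidecar(path), simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != 2)
      stop("field TIFF '", path, "' must have exactly two pages (x, y)")
    x <- pages[[1]] * meta$scale[1] + meta$offset[1]
    y <- pages[[2]] * meta$scale[2] + meta$offset[2]
    if (!identical(dim(x), dim(y)))
      stop("component shape mismatch in field '", path, "'")
    VectorField2D(x, y, meta$units, meta$spacing_um)
  } else if (ext == "csv") {
    hdr <- readLines(path, n = 10)
    hdr <- hdr[startsWith(hdr, "#")]
    getval <- function(key) {
      ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
      if (!length(ln))
        stop("field CSV '", path, "' is missing '", key, "' metadata")
      sub(paste0("^# ", key, "="), "", ln[1])
    }
    units <- getval("units")
    spacing <- as.numeric(getval("spacing_um"))
    df <- utils::read.csv(path, comment.char = "#")
    need <- c("x_px", "y_px", "comp_x", "comp_y")
    if (!all(need %in% names(df)))
      stop("field CSV '", path, "' must have columns ",
           paste(need, collapse = ", "))
    nr <- max(df$y_px) + 1L; nc <- max(df$x_px) + 1L
    if (nrow(df) != nr * nc)
      stop("field CSV '", path, "' does not cover a full ", nr, "x", nc,
           " grid")
    x <- matrix(NA_real_, nr, nc); y <- matrix(NA_real_, nr, nc)
    lin <- df$y_px + 1L + nr * df$x_px
    x[lin] <- df$comp_x
    y[lin] <- df$comp_y
    VectorField2D(x, y, units, spacing)
  } else {
    stop("unsupported field format: .", ext)
  }
}

#' Serialize a solve result to JSON
#'
#' @param res a [SolveResult-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSolveResultJSON <- function(res, path) {
  jsonlite::write_json(
    list(iterations = res@iterations, converged = res@converged,
         residual_l2_um = res@residualL2, residual_l1_um = res@residualL1,
         penalty_l2_Pa = res@penaltyL2, penalty_l1_Pa = res@penaltyL1,
         objective = utils::tail(res@objectiveTrace, 1)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
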