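# Colour-change feature extraction from before/after array scans.
#
# The readout is difference imaging: for each spot and channel,
# delta = |mean(after) - mean(before)| over the disc of pixels at the spot
# centre. Concatenated channel-major over the N spots this gives the
# 3N-dimensional colour-change profile.

# 0-based (dRow, dCol) offsets of lattice points within Euclidean distance
# radiusPx of the origin.
.discOffsets <- function(radiusPx) {
  r <- as.integer(radiusPx)
  g <- expand.grid(dRow = -r:r, dCol = -r:r)
  as.matrix(g[g$dRow^2 + g$dCol^2 <= r^2, , drop = FALSE])
}

#' Pixels in a disc mask
#'
#' Number of integer pixel positions whose Euclidean distance from the spot
#' centre is at most \code{radiusPx}. This is the averaging support used by
#' \code{\link{spotMeanColor}}; it is a fixed constant per radius,
#' independent of spot or image. At the default radius of 12 px it is 441
#' pixels. (Published spot-averaging protocols sometimes quote slightly
#' different counts for a nominal radius; the distance-\eqn{\le}-radius
#' lattice convention used here is stated explicitly so the support is
#' unambiguous.)
#'
#' @param radiusPx disc radius in pixels.
#' @return integer pixel count.
#' @examples
#' discPixelCount(12)  # 441
#' @export
discPixelCount <- function(radiusPx) nrow(.discOffsets(radiusPx))

#' Lay out spot centres on a regular lattice
#'
#' Deterministic layout-driven localization: arrays are printed at known
#' positions, so centres are computed from the grid geometry rather than
#' detected from image content. Coordinates are 0-based (row, col), row
#' increasing downward; spots are ordered row-major.
#'
#' @param rows,cols grid dimensions (defaults 4 x 3 = 12 spots).
#' @param radiusPx spot radius in pixels (default 12).
#' @param spacing centre-to-centre distance in pixels (default 48).
#' @param margin (row, col) of the first spot centre; default puts it
#'   \code{radiusPx + 5} pixels in from the top-left corner.
#' @return a \linkS4class{SpotGrid}.
#' @examples
#' locateSpots()  # 12 centres
#' @export
locateSpots <- function(rows = 4L, cols = 3L, radiusPx = 12L, spacing = 48L,
                        margin = NULL) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  radiusPx <- as.integer(radiusPx); spacing <- as.integer(spacing)
  if (rows < 1L || cols < 1L) .stopf("rows and cols must be >= 1")
  if (rows * cols > 1L && spacing <= 2L * radiusPx)
    .stopf("layout error: spacing (%d) must exceed 2*radiusPx (%d) or discs overlap",
           spacing, 2L * radiusPx)
  if (is.null(margin)) margin <- c(radiusPx + 5L, radiusPx + 5L)
  centers <- as.matrix(expand.grid(col = margin[2] + (seq_len(cols) - 1L) * spacing,
                                   row = margin[1] + (seq_len(rows) - 1L) * spacing))
  centers <- centers[, c("row", "col"), drop = FALSE]
  obj <- new("SpotGrid", rows = rows, cols = cols,
             centers = unname(centers), radiusPx = radiusPx)
  validObject(obj)
  obj
}

#' Mean colour over a spot disc
#'
#' Per-channel arithmetic mean over all pixels whose integer position lies
#' within Euclidean distance \code{radiusPx} of \code{center}
#' (\code{\link{discPixelCount}} pixels). Radius 0 returns the centre pixel.
#'
#' @param image a \linkS4class{SensorArrayImage}.
#' @param center 0-based (row, col) spot centre.
#' @param radiusPx disc radius in pixels.
#' @return numeric (R, G, B) means.
#' @export
spotMeanColor <- function(image, center, radiusPx) {
  d <- dim(image@pixels)
  off <- .discOffsets(radiusPx)
  rows <- center[1] + off[, 1] + 1L
  cols <- center[2] + off[, 2] + 1L
  if (min(rows) < 1L || min(cols) < 1L || max(rows) > d[1] || max(cols) > d[2])
    .stopf("spot disc at (%d, %d) radius %d extends outside the %d x %d image",
           center[1], center[2], radiusPx, d[1], d[2])
  vapply(1:3, function(ch) mean(image@pixels[cbind(rows, cols, ch)]), numeric(1))
}

#' Colour-change profile of a before/after image pair
#'
#' For every spot of \code{grid} and every channel, the absolute difference
#' of the disc-mean colours of the two images. By the absolute value the
#' result is symmetric in the two images. Output is channel-major: all
#' delta-R values (spots in grid order), then delta-G, then delta-B.
#'
#' @param before,after \linkS4class{SensorArrayImage}s of identical size.
#' @param grid a \linkS4class{SpotGrid}.
#' @return named numeric vector of length \code{3 * nSpots}, entries in
#'   [0, 255].
#' @export
differenceProfile <- function(before, after, grid) {
  if (!identical(dim(before@pixels), dim(after@pixels)))
    .stopf("before and after images differ in size")
  n <- nrow(grid@centers)
  mb <- t(vapply(seq_len(n), function(i)
    spotMeanColor(before, grid@centers[i, ], grid@radiusPx), numeric(3)))
  ma <- t(vapply(seq_len(n), function(i)
    spotMeanColor(after, grid@centers[i, ], grid@radiusPx), numeric(3)))
  prof <- as.vector(abs(ma - mb))  # column-major over channels = channel-major
  names(prof) <- .featureNames(n)
  prof
}

#' Read or write an 8-bit RGB array scan
#'
#' PNG via the \pkg{png} package; TIFF via \pkg{tiff} when installed.
#' Channel values are stored at 8-bit depth, so a round trip quantizes to
#' integers in [0, 255].
#'
#' @param path file path ending in \code{.png}, \code{.tif} or \code{.tiff}.
#' @param phase exposure phase recorded on the returned image.
#' @param dpi resolution metadata.
#' @return \code{readArrayImage}: a \linkS4class{SensorArrayImage}.
#' @export
readArrayImage <- function(path, phase = c("before", "after"), dpi = 400L) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        .stopf("the 'tiff' package is required to read %s", path)
      tiff::readTIFF(path)
    },
    .stopf("unsupported image format '.%s'", ext))
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  px <- px[, , 1:3, drop = FALSE]  # drop alpha if present
  SensorArrayImage(round(px * 255), match.arg(phase), dpi)
}

#' @rdname readArrayImage
#' @param image a \linkS4class{SensorArrayImage} to write.
#' @return \code{writeArrayImage}: the path, invisibly.
#' @export
writeArrayImage <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  px <- image@pixels / 255
  switch(ext,
    png = png::writePNG(px, path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        .stopf("the 'tiff' package is required to write %s", path)
      tiff::writeTIFF(px, path, bits.per.sample = 8L)
    },
    .stopf("unsupported image format '.%s'", ext))
  invisible(path)
}

#' Read or write a profile feature table
#'
#' CSV with the exact header \code{sample_id, level, category, dye01_dR,
#' ..., dyeNN_dB} (feature columns channel-major). The round trip is
#' lossless for features, labels and fractions.
#'
#' @param path CSV file path.
#' @return \code{readProfileTable}: a \linkS4class{SensorProfileSet}.
#' @export
readProfileTable <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("sample_id", "level", "category")
  if (!identical(head(colnames(df), 3L), meta))
    .stopf("format error: first columns must be %s", paste(meta, collapse = ", "))
  feat <- setdiff(colnames(df), meta)
  if (length(feat) %% 3L != 0L)
    .stopf("format error: %d feature columns (not a multiple of 3)", length(feat))
  nDyes <- length(feat) %/% 3L
  want <- .featureNames(nDyes)
  if (!identical(feat, want)) {
    missing <- setdiff(want, feat); extra <- setdiff(feat, want)
    .stopf("format error: feature columns do not match the dye01_dR..dye%02d_dB scheme%s%s",
           nDyes,
           if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")) else "",
           if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")) else "")
  }
  prof <- t(as.matrix(df[, feat, drop = FALSE]))
  rownames(prof) <- feat
  SensorProfileSet(prof, level = df$level, sampleId = df$sample_id,
                   provenance = list(source = path))
}

#' @rdname readProfileTable
#' @param x a \linkS4class{SensorProfileSet} to write.
#' @return \code{writeProfileTable}: the path, invisibly.
#' @export
writeProfileTable <- function(x, path) {
  df <- data.frame(sample_id = colData(x)$sample_id,
                   level = adulterationLevel(x),
                   category = as.character(sampleCategory(x)),
                   profileMatrix(x), check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
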