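# Readers/writers and the two core containers: calibrated single-channel
# images and neuronal process traces.

PUNCTUM_COLUMNS <- c(
  "punctum_id", "image_id", "centroid_x_um", "centroid_y_um", "area_um2",
  "distance_um", "process_id", "mean_marker", "mean_signal",
  "signal_over_marker"
)

#' Calibrated single-channel image
#'
#' A 2-D intensity grid plus the pixel-size calibration every micrometre
#' quantity in the pipeline derives from. Rows index y (increasing downward),
#' columns index x; the centre of pixel `[r, c]` sits at
#' `((c - 0.5) * pixel_size, (r - 0.5) * pixel_size)` um.
#'
#' @param pixels numeric matrix of finite, non-negative intensities.
#' @param pixel_size calibration in um/pixel (> 0).
#' @param channel_label free-text channel name (e.g. "synaptophysin",
#'   "SNAP29").
#' @return an object of class `channel_image`.
#' @export
channel_image <- function(pixels, pixel_size, channel_label = "") {
  if (!is.matrix(pixels) || nrow(pixels) < 1 || ncol(pixels) < 1) {
    stop("pixels must be a matrix with at least 1x1 entries")
  }
  if (!all(is.finite(pixels))) stop("image intensities must be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    stop("pixel_size must be a single positive number (um/pixel)")
  }
  structure(
    list(pixels = pixels, pixel_size = pixel_size,
         channel_label = channel_label),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf(
    "<channel_image> %dx%d px, %.4g um/px, label '%s', range [%.4g, %.4g]\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$channel_label,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' Read a single-channel grayscale TIFF
#'
#' Calibration is supplied by the caller, not parsed from TIFF tags (tag
#' dialects are unreliable). Integer TIFFs are read at native bit depth.
#'
#' @param path file path to a 2-D single-channel TIFF.
#' @param pixel_size calibration in um/pixel.
#' @param channel_label optional channel name.
#' @return a [channel_image].
#' @export
read_channel_image <- function(path, pixel_size, channel_label = "") {
  if (missing(pixel_size) || is.null(pixel_size)) {
    stop("pixel_size (um/pixel) must be supplied to read_channel_image()")
  }
  if (!file.exists(path)) stop("no such file: ", path)
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) != 2) {
    stop(sprintf(
      "expected a single-channel 2-D image, got shape %s in %s",
      paste(dim(px), collapse = "x"), path
    ))
  }
  storage.mode(px) <- "double"
  img <- channel_image(px, pixel_size, channel_label)
  attr(img, "bits_per_sample") <- attr(px, "bits.per.sample")
  img
}

#' Write a channel image as an integer grayscale TIFF
#'
#' Intensities are rounded and clipped to the integer range of the requested
#' bit depth, so a write/read round trip of integer-valued data is exact.
#'
#' @param img a [channel_image].
#' @param path output path.
#' @param bits bits per sample (8 or 16).
#' @export
write_channel_image <- function(img, path, bits = 16L) {
  stopifnot(inherits(img, "channel_image"), bits %in% c(8L, 16L))
  maxv <- 2^bits - 1
  m <- pmin(pmax(round(img$pixels), 0), maxv)
  tiff::writeTIFF(m / maxv, path, bits.per.sample = as.integer(bits),
                  compression = "none")
  invisible(path)
}

#' Neuronal process traces
#'
#' Holds the manually (or synthetically) traced process geometry in both
#' representations the pipeline needs: polylines in micrometres for distance
#' and arc-length computations, and a rasterized single-pixel-wide mask.
#'
#' @param polylines list of two-column matrices (columns x, y in um), one per
#'   process; may be empty.
#' @param pixel_size calibration in um/pixel.
#' @param image_shape integer vector `c(rows, cols)`; required to rasterize
#'   non-empty polylines.
#' @return an object of class `process_traces` with elements `polylines`,
#'   `mask`, `lengths` (per-process um), `total_length`, `pixel_size`,
#'   `image_shape`.
#' @export
process_traces <- function(polylines, pixel_size, image_shape = NULL) {
  stopifnot(pixel_size > 0)
  polylines <- lapply(polylines, function(p) {
    p <- as.matrix(p)
    if (nrow(p) < 2) stop("each polyline needs at least 2 vertices")
    colnames(p) <- c("x", "y")
    p
  })
  lengths <- vapply(polylines, polyline_length, numeric(1))
  mask <- NULL
  if (length(polylines) > 0) {
    if (is.null(image_shape)) {
      stop("image_shape is required to rasterize non-empty traces")
    }
    mask <- rasterize_polylines(polylines, pixel_size, image_shape)
  } else if (!is.null(image_shape)) {
    mask <- matrix(FALSE, image_shape[1], image_shape[2])
  }
  structure(
    list(polylines = polylines, mask = mask, lengths = lengths,
         total_length = sum(lengths), pixel_size = pixel_size,
         image_shape = image_shape),
    class = "process_traces"
  )
}

#' @export
print.process_traces <- function(x, ...) {
  cat(sprintf("<process_traces> %d process(es), total length %.2f um\n",
              length(x$polylines), x$total_length))
  invisible(x)
}

#' Rasterize polylines to a single-pixel-wide mask
#'
#' A pixel belongs to the mask iff its centre lies within `pixel_size / 2`
#' of some polyline.
#'
#' @keywords internal
rasterize_polylines <- function(polylines, pixel_size, image_shape) {
  nr <- image_shape[1]
  nc <- image_shape[2]
  mask <- matrix(FALSE, nr, nc)
  half <- pixel_size / 2 + 1e-12
  for (poly in polylines) {
    samp <- sample_polyline(poly, step = pixel_size / 4)
    rr <- pmin(pmax(round(samp$y / pixel_size + 0.5), 1), nr)
    cc <- pmin(pmax(round(samp$x / pixel_size + 0.5), 1), nc)
    cand <- unique(cbind(
      rep(rr, each = 9) + rep(c(-1L, 0L, 1L), times = 3),
      rep(cc, each = 9) + rep(rep(c(-1L, 0L, 1L), each = 3), times = 1)
    ))
    keep <- cand[, 1] >= 1 & cand[, 1] <= nr & cand[, 2] >= 1 & cand[, 2] <= nc
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) next
    ctr <- pixel_centers_um(cand[, 1], cand[, 2], pixel_size)
    d <- dist_points_polyline(ctr, poly)
    hit <- cand[d <= half, , drop = FALSE]
    mask[hit] <- TRUE
  }
  mask
}

#' Read process traces from a polyline CSV or a binary mask TIFF
#'
#' The CSV schema is `process_id, vertex_index, x_um, y_um`, one row per
#' vertex. A TIFF input is interpreted as a binary mask (non-zero =
#' process); mask-only traces support distance filtering but have no
#' polylines, hence no arc-length quantities.
#'
#' @param path CSV or TIFF file.
#' @param pixel_size calibration in um/pixel.
#' @param image_shape `c(rows, cols)`; required for CSV input so the mask
#'   can be rasterized and vertex bounds checked.
#' @return a [process_traces] object.
#' @export
read_traces <- function(path, pixel_size, image_shape = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    px <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(px)) != 2) stop("trace mask must be single-channel 2-D")
    tr <- process_traces(list(), pixel_size, dim(px))
    tr$mask <- px != 0
    return(tr)
  }
  if (file.size(path) == 0) {
    return(process_traces(list(), pixel_size, image_shape))
  }
  df <- utils::read.csv(path)
  if (nrow(df) == 0) {
    return(process_traces(list(), pixel_size, image_shape))
  }
  need <- c("process_id", "vertex_index", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (!is.null(image_shape)) {
    xmax <- image_shape[2] * pixel_size
    ymax <- image_shape[1] * pixel_size
    bad <- df$x_um < 0 | df$x_um > xmax | df$y_um < 0 | df$y_um > ymax
    if (any(bad)) {
      stop(sprintf("%d trace vertex(es) fall outside the image extent", sum(bad)))
    }
  }
  polys <- lapply(split(df, df$process_id), function(g) {
    g <- g[order(g$vertex_index), ]
    if (nrow(g) < 2) {
      stop("polyline for process ", g$process_id[1], " has fewer than 2 vertices")
    }
    cbind(x = g$x_um, y = g$y_um)
  })
  polys <- polys[order(as.numeric(names(polys)))]
  process_traces(unname(polys), pixel_size, image_shape)
}

#' Write process traces as a polyline CSV
#'
#' @param traces a [process_traces] object (must have polylines).
#' @param path output CSV path.
#' @export
write_traces <- function(traces, path) {
  rows <- lapply(seq_along(traces$polylines), function(i) {
    p <- traces$polylines[[i]]
    data.frame(process_id = i, vertex_index = seq_len(nrow(p)),
               x_um = p[, 1], y_um = p[, 2])
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(process_id = integer(), vertex_index = integer(),
               x_um = numeric(), y_um = numeric())
  df$x_um <- sprintf("%.9f", df$x_um)
  df$y_um <- sprintf("%.9f", df$y_um)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a punctum table with the canonical column order
#'
#' The per-pixel sets carried by detected tables (attribute `"pixels"`) are
#' not serialized; the CSV holds the tabular record only.
#'
#' @param table a punctum data.frame (see [detect_puncta]).
#' @param path output CSV path.
#' @export
write_punctum_table <- function(table, path) {
  missing_cols <- setdiff(PUNCTUM_COLUMNS, names(table))
  if (length(missing_cols)) {
    stop("punctum table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(table[, PUNCTUM_COLUMNS, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a punctum table written by [write_punctum_table]
#'
#' @param path CSV path.
#' @return data.frame in canonical column order.
#' @export
read_punctum_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    punctum_id = "integer", image_id = "character",
    centroid_x_um = "numeric", centroid_y_um = "numeric",
    area_um2 = "numeric", distance_um = "numeric", process_id = "integer",
    mean_marker = "numeric", mean_signal = "numeric",
    signal_over_marker = "numeric"
  ))
  df[, PUNCTUM_COLUMNS, drop = FALSE]
}

#' An empty punctum table with the canonical schema
#'
#' @param image_id image identifier recycled into the (empty) table.
#' @return zero-row data.frame.
#' @export
empty_punctum_table <- function(image_id = character(0)) {
  data.frame(
    punctum_id = integer(0), image_id = character(0),
    centroid_x_um = numeric(0), centroid_y_um = numeric(0),
    area_um2 = numeric(0), distance_um = numeric(0),
    process_id = integer(0), mean_marker = numeric(0),
    mean_signal = numeric(0), signal_over_marker = numeric(0)
  )
}
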