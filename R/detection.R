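# Presynaptic-site detection: normalize -> global threshold -> 8-connected
# component labeling -> area and process-distance filters.

#' Detection parameters
#'
#' Defaults follow the published segmentation rules: connected components
#' with area outside 0.35-10 um^2 are removed, as are components farther
#' than 1 um from every traced process. All bounds are inclusive: a
#' component at exactly 0.35 or 10 um^2, or exactly 1 um away, is kept.
#'
#' @param threshold_mode "auto" (inter-class-variance maximization over the
#'   256-bin histogram of the normalized image) or "fixed".
#' @param fixed_threshold threshold on the 0-255 normalized scale; required
#'   when `threshold_mode = "fixed"`.
#' @param min_area,max_area area window in um^2.
#' @param max_distance maximum distance to a process in um.
#' @param distance_mode "min_pixel" (minimum over component pixel centres;
#'   default) or "centroid".
#' @param connectivity pixel connectivity; only 8 is supported (kept
#'   explicit because it is a stated property of the method).
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(threshold_mode = c("auto", "fixed"),
                             fixed_threshold = NULL,
                             min_area = 0.35, max_area = 10,
                             max_distance = 1.0,
                             distance_mode = c("min_pixel", "centroid"),
                             connectivity = 8L) {
  threshold_mode <- match.arg(threshold_mode)
  distance_mode <- match.arg(distance_mode)
  if (connectivity != 8L) stop("only 8-connectivity is supported")
  if (!(min_area > 0 && min_area < max_area)) {
    stop("need 0 < min_area < max_area")
  }
  if (max_distance <= 0) stop("max_distance must be > 0")
  if (threshold_mode == "fixed") {
    if (is.null(fixed_threshold) || !is.numeric(fixed_threshold) ||
        fixed_threshold < 0 || fixed_threshold > 255) {
      stop("fixed_threshold must lie in [0, 255]")
    }
  }
  structure(
    list(threshold_mode = threshold_mode, fixed_threshold = fixed_threshold,
         connectivity = 8L, min_area = min_area, max_area = max_area,
         max_distance = max_distance, distance_mode = distance_mode),
    class = "detection_params"
  )
}

#' Min-max normalize an image to the 0-255 range
#'
#' Linear rescale mapping the image minimum to 0 and maximum to 255. A
#' constant image carries no detectable structure and maps to all zeros.
#' The input object is not modified.
#'
#' @param img a [channel_image].
#' @return a new [channel_image] with range exactly \[0, 255\] (or all 0).
#' @export
normalize_image <- function(img) {
  stopifnot(inherits(img, "channel_image"))
  lo <- min(img$pixels)
  hi <- max(img$pixels)
  px <- if (hi > lo) (img$pixels - lo) / (hi - lo) * 255 else
    matrix(0, nrow(img$pixels), ncol(img$pixels))
  channel_image(px, img$pixel_size, img$channel_label)
}

#' Global threshold by inter-class-variance maximization
#'
#' Otsu's criterion over the 256-bin histogram of a 0-255 image: the
#' threshold t (a bin edge in 0..254) maximizing
#' w0(t) * w1(t) * (mu0(t) - mu1(t))^2, ties broken toward the lowest t.
#'
#' @param pixels numeric matrix with values in \[0, 255\].
#' @return the selected threshold (intensities strictly above it are
#'   foreground).
#' @export
otsu_threshold <- function(pixels) {
  v <- pmin(pmax(floor(pixels), 0), 255)
  counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  bins <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * bins)
  mu_total <- mu[256]
  t_cand <- 1:255                      # class split after bin t_cand - 1
  w0c <- w0[t_cand]
  num <- (mu_total * w0c - mu[t_cand])^2
  den <- w0c * (1 - w0c)
  bcv <- ifelse(den > 0, num / den, -Inf)
  if (all(!is.finite(bcv))) return(0)
  bins[t_cand][which.max(bcv)]
}

#' Binarize a normalized image with a global threshold
#'
#' Foreground is strictly above the threshold, so an all-background image
#' yields an empty mask for any threshold >= 0.
#'
#' @param img a [channel_image] normalized to \[0, 255\].
#' @param params a [detection_params]; in auto mode the threshold comes from
#'   [otsu_threshold] and is recorded in the `"threshold"` attribute.
#' @return logical mask with attributes `threshold` and `threshold_mode`.
#' @export
binarize <- function(img, params = detection_params()) {
  stopifnot(inherits(img, "channel_image"))
  if (min(img$pixels) < 0 || max(img$pixels) > 255) {
    stop("binarize() expects an image normalized to [0, 255]; see normalize_image()")
  }
  thr <- if (params$threshold_mode == "auto") otsu_threshold(img$pixels) else {
    if (params$fixed_threshold < 0 || params$fixed_threshold > 255) {
      stop("fixed_threshold must lie in [0, 255]")
    }
    params$fixed_threshold
  }
  mask <- img$pixels > thr
  attr(mask, "threshold") <- thr
  attr(mask, "threshold_mode") <- params$threshold_mode
  mask
}

#' Label 8-connected foreground components
#'
#' Two foreground pixels belong to the same object iff they adjoin
#' horizontally, vertically, or diagonally. Labels are deterministic:
#' components are numbered by the raster-scan (row-major) order of their
#' first pixel.
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity only 8 is supported.
#' @return list with `labels` (integer matrix, 0 = background), `pixels`
#'   (list of two-column row/col index matrices per component, in raster
#'   order of first pixel), and `n` (component count).
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (connectivity != 8L) stop("only 8-connectivity is supported")
  mask <- mask != 0
  nr <- nrow(mask)
  nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  fg <- which(mask)
  n_fg <- length(fg)
  if (n_fg == 0) return(list(labels = labels, pixels = list(), n = 0L))

  # id of each foreground pixel (0 for background), column-major like `which`
  id_of <- matrix(0L, nr, nc)
  id_of[fg] <- seq_len(n_fg)
  fr <- ((fg - 1L) %% nr) + 1L
  fc <- ((fg - 1L) %/% nr) + 1L

  parent <- seq_len(n_fg)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  # raster (row-major) scan; union with the 4 already-visited neighbours
  ord <- order(fr, fc)
  for (k in ord) {
    r <- fr[k]; c <- fc[k]
    rk <- find(k)
    if (c > 1L && id_of[r, c - 1L] > 0L) {
      rn <- find(id_of[r, c - 1L]); if (rn != rk) { parent[rn] <- rk }
    }
    if (r > 1L) {
      for (dc in -1L:1L) {
        cc <- c + dc
        if (cc >= 1L && cc <= nc && id_of[r - 1L, cc] > 0L) {
          rn <- find(id_of[r - 1L, cc])
          rk <- find(k)
          if (rn != rk) parent[rn] <- rk
        }
      }
    }
  }
  root <- vapply(seq_len(n_fg), find, integer(1))

  # renumber components by raster order of their first pixel
  first_rank <- rep.int(.Machine$integer.max, n_fg)
  rank_rm <- integer(n_fg)
  rank_rm[ord] <- seq_len(n_fg)
  for (k in seq_len(n_fg)) {
    rt <- root[k]
    if (rank_rm[k] < first_rank[rt]) first_rank[rt] <- rank_rm[k]
  }
  roots <- unique(root)
  roots <- roots[order(first_rank[roots])]
  new_label <- integer(n_fg)
  new_label[roots] <- seq_along(roots)
  lab <- new_label[root]
  labels[fg] <- lab

  pix <- vector("list", length(roots))
  for (i in seq_along(roots)) {
    sel <- lab == i
    pix[[i]] <- cbind(row = fr[sel], col = fc[sel])
  }
  list(labels = labels, pixels = pix, n = length(roots))
}

#' Distance from a connected component to the traced processes
#'
#' @param pixels two-column row/col index matrix of the component.
#' @param traces a [process_traces] object (may be empty: distance `Inf`).
#' @param pixel_size calibration in um/pixel.
#' @param mode "min_pixel" (minimum over all pixel centres) or "centroid".
#' @return list with `distance_um` and `process_id` (NA when no traces).
#' @export
component_distance <- function(pixels, traces, pixel_size,
                               mode = c("min_pixel", "centroid")) {
  mode <- match.arg(mode)
  if (is.null(pixels) || nrow(pixels) == 0) stop("empty component")
  pts <- pixel_centers_um(pixels[, 1], pixels[, 2], pixel_size)
  if (mode == "centroid") {
    pts <- matrix(colMeans(pts), nrow = 1)
  }
  d <- dist_points_traces(pts, traces)
  i <- which.min(d$distance)
  list(distance_um = d$distance[i], process_id = d$process_id[i])
}

#' Detect presynaptic puncta on the marker channel
#'
#' Runs the full segmentation pipeline on the marker (synaptophysin)
#' channel: min-max normalization to 0-255, global threshold binarization,
#' 8-connected component labeling, then the area window and
#' process-distance filters (inclusive bounds). Kept components are
#' measured on both raw channels: `mean_marker` and `mean_signal` are mean
#' raw intensities over the component's pixel set, so cross-condition
#' intensity comparisons are not distorted by the per-image rescaling used
#' for thresholding.
#'
#' @param marker marker-channel [channel_image] (detection channel).
#' @param signal signal-channel [channel_image]; same shape and
#'   calibration.
#' @param traces a [process_traces] object.
#' @param params a [detection_params].
#' @param image_id identifier stored in the table.
#' @return data.frame with columns `punctum_id, image_id, centroid_x_um,
#'   centroid_y_um, area_um2, distance_um, process_id, mean_marker,
#'   mean_signal, signal_over_marker`; attribute `"pixels"` holds the kept
#'   components' pixel sets, attribute `"log"` the threshold used and the
#'   per-rule removal counts, attribute `"pixel_size"` the calibration.
#' @export
detect_puncta <- function(marker, signal, traces,
                          params = detection_params(), image_id = "image") {
  stopifnot(inherits(marker, "channel_image"), inherits(signal, "channel_image"))
  if (!identical(dim(marker$pixels), dim(signal$pixels))) {
    stop("marker and signal images differ in shape")
  }
  if (marker$pixel_size != signal$pixel_size) {
    stop("marker and signal images differ in pixel_size calibration")
  }
  ps <- marker$pixel_size

  norm <- normalize_image(marker)
  mask <- binarize(norm, params)
  lab <- label_components(mask)

  n <- lab$n
  log <- list(
    threshold = attr(mask, "threshold"),
    threshold_mode = attr(mask, "threshold_mode"),
    n_components = n,
    removed_small_area = 0L, removed_large_area = 0L,
    removed_distance = 0L, removed_total = 0L, kept = 0L
  )
  out <- empty_punctum_table()
  if (n == 0) {
    attr(out, "pixels") <- list()
    attr(out, "log") <- log
    attr(out, "pixel_size") <- ps
    return(out)
  }

  # distances of every foreground pixel to the traces, then per-component min
  fg_rc <- do.call(rbind, lab$pixels)
  comp_of <- rep.int(seq_len(n), vapply(lab$pixels, nrow, integer(1)))
  area <- vapply(lab$pixels, nrow, integer(1)) * ps^2
  cent <- t(vapply(lab$pixels, function(p) {
    colMeans(pixel_centers_um(p[, 1], p[, 2], ps))
  }, numeric(2)))

  if (params$distance_mode == "min_pixel") {
    dd <- dist_points_traces(pixel_centers_um(fg_rc[, 1], fg_rc[, 2], ps), traces)
    dist_um <- rep(Inf, n)
    proc_id <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      sel <- comp_of == i
      j <- which.min(dd$distance[sel])
      dist_um[i] <- dd$distance[sel][j]
      proc_id[i] <- dd$process_id[sel][j]
    }
  } else {
    dd <- dist_points_traces(cent, traces)
    dist_um <- dd$distance
    proc_id <- dd$process_id
  }

  mean_marker <- vapply(lab$pixels, function(p) mean(marker$pixels[p]), numeric(1))
  mean_signal <- vapply(lab$pixels, function(p) mean(signal$pixels[p]), numeric(1))

  # inclusive bounds with a relative guard so pixel-count x pixel_size^2
  # areas that are exactly on a boundary are not lost to float round-off
  tol <- 1e-9
  too_small <- area < params$min_area * (1 - tol)
  too_large <- area > params$max_area * (1 + tol)
  too_far <- dist_um > params$max_distance * (1 + tol)
  keep <- !(too_small | too_large | too_far)

  log$removed_small_area <- sum(too_small)
  log$removed_large_area <- sum(too_large)
  log$removed_distance <- sum(too_far)
  log$removed_total <- sum(!keep)
  log$kept <- sum(keep)

  ki <- which(keep)
  out <- data.frame(
    punctum_id = seq_along(ki),
    image_id = rep(image_id, length(ki)),
    centroid_x_um = cent[ki, 1], centroid_y_um = cent[ki, 2],
    area_um2 = area[ki], distance_um = dist_um[ki],
    process_id = proc_id[ki],
    mean_marker = mean_marker[ki], mean_signal = mean_signal[ki],
    signal_over_marker = ifelse(mean_marker[ki] > 0,
                                mean_signal[ki] / mean_marker[ki], NA_real_)
  )
  rownames(out) <- NULL
  attr(out, "pixels") <- lab$pixels[ki]
  attr(out, "log") <- log
  attr(out, "pixel_size") <- ps
  out
}

#' Recall and precision of a detection against simulation ground truth
#'
#' Uses centre-coverage matching, which is robust to puncta that merge into
#' a single component (the pipeline deliberately performs no watershed
#' splitting): a true on-process punctum is recalled iff the pixel
#' containing its centre belongs to some kept component, and a kept
#' component is a true positive iff it covers at least one such centre.
#' Many-to-one matches are allowed in both directions.
#'
#' @param table a detection result from [detect_puncta] (with its `"pixels"`
#'   attribute).
#' @param truth ground-truth data.frame from [render_image_pair].
#' @param image_shape `c(rows, cols)` of the analyzed image.
#' @return list with `recall`, `precision`, `n_truth`, `n_detected`.
#' @export
evaluate_detection <- function(table, truth, image_shape) {
  ps <- attr(table, "pixel_size")
  pix <- attr(table, "pixels")
  if (is.null(ps) || is.null(pix)) {
    stop("table must come from detect_puncta() (pixels attribute required)")
  }
  tp <- truth[truth$type == "punctum" & truth$on_process, , drop = FALSE]
  n_truth <- nrow(tp)
  n_det <- nrow(table)
  if (n_truth == 0) {
    return(list(recall = NA_real_, precision = if (n_det == 0) NA_real_ else 0,
                n_truth = 0L, n_detected = n_det))
  }
  lab <- matrix(0L, image_shape[1], image_shape[2])
  for (i in seq_along(pix)) lab[pix[[i]]] <- i
  rr <- pmin(pmax(ceiling(tp$y_um / ps), 1), image_shape[1])
  cc <- pmin(pmax(ceiling(tp$x_um / ps), 1), image_shape[2])
  hit_label <- lab[cbind(rr, cc)]
  recall <- mean(hit_label > 0)
  precision <- if (n_det == 0) NA_real_ else
    length(unique(hit_label[hit_label > 0])) / n_det
  list(recall = recall, precision = precision,
       n_truth = n_truth, n_detected = n_det)
}
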