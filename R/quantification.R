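# Per-punctum and per-image quantification: densities per micron of
# process, two-channel colocalization, marker-normalized SNAP29 intensity,
# and the accumulation index along processes.

#' Puncta density per micron of process
#'
#' @param table punctum table (typically from [detect_puncta]).
#' @param traces a [process_traces] with positive total length.
#' @return list with `per_image` (count / total process length, 1/um) and
#'   `per_process` (data.frame: `process_id, length_um, n_puncta, rate`).
#' @export
density_per_micron <- function(table, traces) {
  if (length(traces$polylines) == 0 || traces$total_length <= 0) {
    stop("density per micron needs traces with positive total length")
  }
  n_proc <- length(traces$polylines)
  counts <- tabulate(table$process_id[!is.na(table$process_id)], nbins = n_proc)
  per_process <- data.frame(
    process_id = seq_len(n_proc),
    length_um = traces$lengths,
    n_puncta = counts,
    rate = counts / traces$lengths
  )
  list(per_image = nrow(table) / traces$total_length,
       per_process = per_process)
}

#' Colocalize puncta detected independently in two channels
#'
#' A signal-channel punctum is colocalized iff its pixel set overlaps a
#' marker-channel punctum's pixel set by at least one pixel. Each signal
#' punctum matches at most one marker punctum: the one with the largest
#' overlap, ties broken toward the lowest marker punctum id.
#'
#' @param signal_puncta,marker_puncta detection results from
#'   [detect_puncta] run on each channel (their `"pixels"` attributes are
#'   required and must come from images of identical geometry).
#' @param traces optional [process_traces]; when given with positive
#'   length, `coloc_per_micron` is computed.
#' @return list with `pairs` (data.frame `signal_id, marker_id,
#'   overlap_px`), `n_colocalized`, and `coloc_per_micron` (NA without
#'   traces).
#' @export
colocalize <- function(signal_puncta, marker_puncta, traces = NULL) {
  sp <- attr(signal_puncta, "pixels")
  mp <- attr(marker_puncta, "pixels")
  if (is.null(sp) || is.null(mp)) {
    stop("both tables need their 'pixels' attribute (run detect_puncta)")
  }
  ps_s <- attr(signal_puncta, "pixel_size")
  ps_m <- attr(marker_puncta, "pixel_size")
  if (!isTRUE(all.equal(ps_s, ps_m))) {
    stop("punctum tables come from images with different calibrations")
  }
  key <- function(p) p[, 1] * 1e6 + p[, 2]
  mkeys <- lapply(mp, key)
  pairs <- data.frame(signal_id = integer(0), marker_id = integer(0),
                      overlap_px = integer(0))
  for (i in seq_along(sp)) {
    sk <- key(sp[[i]])
    ov <- vapply(mkeys, function(mk) sum(sk %in% mk), integer(1))
    if (length(ov) && any(ov > 0)) {
      j <- which.max(ov)  # which.max takes the first (lowest) index on ties
      pairs <- rbind(pairs, data.frame(
        signal_id = signal_puncta$punctum_id[i],
        marker_id = marker_puncta$punctum_id[j],
        overlap_px = ov[j]
      ))
    }
  }
  cpm <- NA_real_
  if (!is.null(traces) && traces$total_length > 0) {
    cpm <- nrow(pairs) / traces$total_length
  }
  list(pairs = pairs, n_colocalized = nrow(pairs), coloc_per_micron = cpm)
}

#' Marker-normalized signal intensity per punctum
#'
#' `ratio = mean_signal / mean_marker` per punctum; puncta with
#' non-positive marker intensity are flagged and excluded (they cannot
#' occur for components detected on the marker channel above a positive
#' threshold, but can for externally supplied tables).
#'
#' @param table punctum table.
#' @return list with `ratio` (per kept punctum), `mean`, `sem`, `n`, and
#'   `n_excluded`.
#' @export
signal_over_marker <- function(table) {
  ok <- table$mean_marker > 0
  ratio <- table$mean_signal[ok] / table$mean_marker[ok]
  list(ratio = ratio, mean = if (length(ratio)) mean(ratio) else NA_real_,
       sem = sem(ratio), n = length(ratio), n_excluded = sum(!ok))
}

#' Signal-intensity profile along each process
#'
#' Samples each polyline at a fixed arc-length step (default half a pixel,
#' below-Nyquist for the pixel grid), interpolates the signal channel
#' bilinearly at each position, and flags which positions fall inside a
#' detected punctum (the position's containing pixel belongs to the
#' punctum's pixel set).
#'
#' @param traces a [process_traces].
#' @param signal signal-channel [channel_image].
#' @param table detection result from [detect_puncta] (pixel sets
#'   required).
#' @param step arc-length step in um (default `pixel_size / 2`).
#' @return data.frame `process_id, s_um, x_um, y_um, intensity,
#'   punctum_id` (0 = shaft position), with attribute `"step"`.
#' @export
accumulation_profile <- function(traces, signal, table,
                                 step = signal$pixel_size / 2) {
  pix <- attr(table, "pixels")
  if (is.null(pix)) stop("table must carry pixel sets (run detect_puncta)")
  ps <- signal$pixel_size
  shape <- dim(signal$pixels)
  lab <- matrix(0L, shape[1], shape[2])
  for (i in seq_along(pix)) lab[pix[[i]]] <- table$punctum_id[i]
  out <- list()
  for (i in seq_along(traces$polylines)) {
    samp <- sample_polyline(traces$polylines[[i]], step)
    inten <- bilinear_interp(signal$pixels, samp$x, samp$y, ps)
    rr <- pmin(pmax(ceiling(samp$y / ps), 1), shape[1])
    cc <- pmin(pmax(ceiling(samp$x / ps), 1), shape[2])
    pid <- lab[cbind(rr, cc)]
    out[[i]] <- data.frame(process_id = i, s_um = samp$s, x_um = samp$x,
                           y_um = samp$y, intensity = inten,
                           punctum_id = pid)
  }
  prof <- if (length(out)) do.call(rbind, out) else
    data.frame(process_id = integer(0), s_um = numeric(0), x_um = numeric(0),
               y_um = numeric(0), intensity = numeric(0),
               punctum_id = integer(0))
  rownames(prof) <- NULL
  attr(prof, "step") <- step
  prof
}

#' Accumulation index of each punctum along its process
#'
#' For punctum k on a process, `AI_k = I_k / (I_k + B_k)` where `I_k` is
#' the mean signal intensity over the punctum's arc-length span and `B_k`
#' the mean over the shaft (non-punctum) positions of the same process. A
#' uniform profile gives AI = 0.5; zero shaft signal gives AI = 1. The
#' index is bounded in \[0, 1\], invariant to a positive rescaling of the
#' whole profile, and monotone in punctum enrichment.
#'
#' @param profile output of [accumulation_profile].
#' @return data.frame `process_id, punctum_id, ai, flag` (flag is "" for a
#'   valid index, "no_shaft" when puncta cover the whole process,
#'   "zero_signal" when `I_k + B_k = 0`).
#' @export
accumulation_index <- function(profile) {
  res <- list()
  for (i in unique(profile$process_id)) {
    pr <- profile[profile$process_id == i, ]
    shaft <- pr$intensity[pr$punctum_id == 0]
    ids <- sort(unique(pr$punctum_id[pr$punctum_id > 0]))
    for (k in ids) {
      I_k <- mean(pr$intensity[pr$punctum_id == k])
      if (length(shaft) == 0) {
        res[[length(res) + 1]] <- data.frame(
          process_id = i, punctum_id = k, ai = NA_real_, flag = "no_shaft")
        next
      }
      B_k <- mean(shaft)
      if (I_k + B_k == 0) {
        res[[length(res) + 1]] <- data.frame(
          process_id = i, punctum_id = k, ai = NA_real_, flag = "zero_signal")
      } else {
        res[[length(res) + 1]] <- data.frame(
          process_id = i, punctum_id = k, ai = I_k / (I_k + B_k), flag = "")
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(process_id = integer(0), punctum_id = integer(0),
               ai = numeric(0), flag = character(0))
  rownames(out) <- NULL
  out
}

#' Per-image summary of the quantification
#'
#' @param table punctum table for one image.
#' @param traces the image's [process_traces].
#' @param profile optional [accumulation_profile] output; enables the AI
#'   summary columns.
#' @param image_id,condition labels copied into the summary.
#' @param coloc_per_micron optional colocalization density to carry along.
#' @return one-row data.frame: counts, density per micron, mean and SEM of
#'   `mean_signal` and of `signal_over_marker`, and (if a profile is
#'   given) mean and SEM of the accumulation index. SEM is `NA` for fewer
#'   than 2 puncta; an empty table yields count 0 and `NA` means rather
#'   than an error.
#' @export
summarize_image <- function(table, traces, profile = NULL,
                            image_id = "image", condition = NA_character_,
                            coloc_per_micron = NA_real_) {
  n <- nrow(table)
  dens <- if (traces$total_length > 0) n / traces$total_length else NA_real_
  som <- signal_over_marker(table)
  ai_mean <- ai_sem <- NA_real_
  if (!is.null(profile)) {
    ai <- accumulation_index(profile)
    ok <- ai$flag == ""
    if (any(ok)) {
      ai_mean <- mean(ai$ai[ok])
      ai_sem <- sem(ai$ai[ok])
    }
  }
  data.frame(
    image_id = image_id, condition = condition, n_puncta = n,
    puncta_per_micron = dens, coloc_per_micron = coloc_per_micron,
    mean_signal_mean = if (n > 0) mean(table$mean_signal) else NA_real_,
    mean_signal_sem = sem(table$mean_signal),
    ratio_mean = som$mean, ratio_sem = som$sem,
    ai_mean = ai_mean, ai_sem = ai_sem
  )
}
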