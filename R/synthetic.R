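# Ground-truthed synthetic two-channel micrographs: smooth neuronal
# processes, PSF-blurred puncta placed along them, off-process distractors,
# sub-threshold speckle, and additive background noise. Stands in for the
# study's (undeposited) confocal images and gives every pipeline stage a
# verifiable target.

#' Simulation configuration
#'
#' Defaults emulate a typical confocal field of cultured cortical neurons
#' at 0.1 um/px: a 51.2 x 51.2 um image, a few smooth processes, puncta
#' placed along them as a homogeneous Poisson process on arc length, and
#' log-normal spot amplitudes. `condition_factor` multiplies the
#' signal-channel (SNAP29) amplitude of every spot, modeling a
#' knockdown/ischemia-like reduction; the marker channel is never scaled.
#'
#' Punctum spots use `psf_sigma` as an effective width (optical PSF
#' convolved with the physical bouton extent); the 0.3 um default puts
#' detected component areas inside the 0.35-10 um^2 analysis window.
#' Speckles use the much narrower `speckle_sigma` so their areas stay below
#' the 0.35 um^2 cutoff. Amplitudes are log-normal truncated at
#' `amplitude_truncation` log-sd, keeping the dimmest puncta above any
#' sensible global threshold (fluorescent labeling below that level would
#' not be scored as a punctum by a human annotator either).
#'
#' @param image_shape integer `c(rows, cols)` in pixels.
#' @param pixel_size um/pixel (> 0).
#' @param n_processes number of neuronal processes to draw.
#' @param process_smoothness direction correlation length of the process
#'   random walk, um.
#' @param puncta_per_micron expected on-process puncta per um of process.
#' @param psf_sigma Gaussian s.d. of punctum/distractor spots, um.
#' @param speckle_sigma Gaussian s.d. of speckle spots, um.
#' @param marker_intensity_dist `c(meanlog, sdlog)` of the log-normal
#'   marker-channel amplitude (arbitrary units).
#' @param signal_intensity_dist `c(meanlog, sdlog)` of the log-normal
#'   signal-channel amplitude.
#' @param amplitude_truncation two-sided truncation of the amplitude
#'   log-normals, in units of sdlog.
#' @param condition_factor multiplicative factor in \[0, 1\] on
#'   signal-channel amplitudes (1 = control).
#' @param distractor_rate expected off-process spots per image.
#' @param distractor_min_distance minimum distance of distractor centres to
#'   any process, um; must exceed the detection distance cutoff plus the
#'   spot radius so the distance filter can remove them.
#' @param speckle_rate expected sub-threshold specks per image.
#' @param background_sigma s.d. of the additive Gaussian background noise
#'   (clipped at 0), arbitrary units.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(image_shape = c(512L, 512L),
                              pixel_size = 0.1,
                              n_processes = 3L,
                              process_smoothness = 5,
                              puncta_per_micron = 0.4,
                              psf_sigma = 0.3,
                              speckle_sigma = 0.09,
                              marker_intensity_dist = c(meanlog = 5.0, sdlog = 0.25),
                              signal_intensity_dist = c(meanlog = 4.8, sdlog = 0.30),
                              amplitude_truncation = 2,
                              condition_factor = 1,
                              distractor_rate = 5,
                              distractor_min_distance = 2,
                              speckle_rate = 20,
                              background_sigma = 7.5,
                              seed = 1L) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (puncta_per_micron < 0) stop("puncta_per_micron must be >= 0")
  if (condition_factor < 0 || condition_factor > 1) {
    stop("condition_factor must lie in [0, 1]")
  }
  if (n_processes < 0) stop("n_processes must be >= 0")
  structure(
    list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
         n_processes = as.integer(n_processes),
         process_smoothness = process_smoothness,
         puncta_per_micron = puncta_per_micron, psf_sigma = psf_sigma,
         speckle_sigma = speckle_sigma,
         marker_intensity_dist = marker_intensity_dist,
         signal_intensity_dist = signal_intensity_dist,
         amplitude_truncation = amplitude_truncation,
         condition_factor = condition_factor,
         distractor_rate = distractor_rate,
         distractor_min_distance = distractor_min_distance,
         speckle_rate = speckle_rate,
         background_sigma = background_sigma, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# truncated log-normal amplitudes (inverse-CDF so draws are reproducible)
.sample_amplitudes <- function(n, dist, trunc_sd) {
  if (n == 0) return(numeric(0))
  meanlog <- dist[[1]]
  sdlog <- dist[[2]]
  plo <- stats::pnorm(-trunc_sd)
  phi <- stats::pnorm(trunc_sd)
  u <- stats::runif(n, plo, phi)
  exp(meanlog + sdlog * stats::qnorm(u))
}

#' Simulate smooth neuronal process traces
#'
#' Each process is a direction-correlated random walk (angle increments
#' with variance step/smoothness) at 0.5 um vertex spacing, started
#' uniformly inside a 2 um margin and steered back toward the image centre
#' whenever it approaches the margin, so polylines stay fully inside the
#' image.
#'
#' @param config a [simulation_config].
#' @return a [process_traces] object.
#' @export
make_process_traces <- function(config) {
  shape <- config$image_shape
  if (any(shape <= 0)) stop("image_shape must have positive extent")
  ps <- config$pixel_size
  xmax <- shape[2] * ps
  ymax <- shape[1] * ps
  margin <- min(2, 0.25 * min(xmax, ymax))
  if (config$n_processes == 0) {
    return(process_traces(list(), ps, shape))
  }
  step <- 0.5
  with_seed(config$seed, {
    polys <- lapply(seq_len(config$n_processes), function(i) {
      target_len <- stats::runif(1, 0.5, 0.9) * min(xmax, ymax)
      n_steps <- max(2L, ceiling(target_len / step))
      x <- stats::runif(1, margin, xmax - margin)
      y <- stats::runif(1, margin, ymax - margin)
      ang <- stats::runif(1, 0, 2 * pi)
      sd_ang <- sqrt(step / config$process_smoothness)
      pts <- matrix(NA_real_, n_steps + 1, 2)
      pts[1, ] <- c(x, y)
      for (k in seq_len(n_steps)) {
        ang <- ang + stats::rnorm(1, 0, sd_ang)
        nx <- x + step * cos(ang)
        ny <- y + step * sin(ang)
        if (nx < margin || nx > xmax - margin ||
            ny < margin || ny > ymax - margin) {
          # steer back toward the centre (with a little noise) and retry
          ang <- atan2(ymax / 2 - y, xmax / 2 - x) + stats::rnorm(1, 0, 0.3)
          nx <- x + step * cos(ang)
          ny <- y + step * sin(ang)
        }
        x <- min(max(nx, margin), xmax - margin)
        y <- min(max(ny, margin), ymax - margin)
        pts[k + 1, ] <- c(x, y)
      }
      pts
    })
    process_traces(polys, ps, shape)
  })
}

# add an isotropic Gaussian spot to an intensity matrix (in place value)
.add_spot <- function(px, x, y, amp, sigma_um, pixel_size) {
  nr <- nrow(px)
  nc <- ncol(px)
  rad <- ceiling(4 * sigma_um / pixel_size) + 1L
  r0 <- max(1L, floor(y / pixel_size + 0.5) - rad)
  r1 <- min(nr, ceiling(y / pixel_size + 0.5) + rad)
  c0 <- max(1L, floor(x / pixel_size + 0.5) - rad)
  c1 <- min(nc, ceiling(x / pixel_size + 0.5) + rad)
  if (r0 > r1 || c0 > c1) return(px)
  rows <- r0:r1
  cols <- c0:c1
  cy <- (rows - 0.5) * pixel_size
  cx <- (cols - 0.5) * pixel_size
  g <- exp(-outer((cy - y)^2, (cx - x)^2, "+") / (2 * sigma_um^2))
  px[rows, cols] <- px[rows, cols] + amp * g
  px
}

#' Render a two-channel synthetic image pair with ground truth
#'
#' Puncta are isotropic Gaussian spots centred at points drawn along the
#' process polylines as a homogeneous Poisson process on arc length; every
#' spot appears in both channels with independent log-normal amplitudes,
#' and the signal-channel amplitude is multiplied by `condition_factor`.
#' Distractors are rejection-sampled farther than
#' `distractor_min_distance` from every process; speckles are narrow spots
#' whose true area falls below the 0.35 um^2 analysis cutoff. Gaussian
#' background noise is added to both channels and clipped at zero.
#'
#' The RNG stream does not depend on `condition_factor`, so two configs
#' differing only in the factor yield an identical marker channel and
#' signal-channel amplitudes scaled exactly by the factor ratio.
#'
#' @param traces a [process_traces] from [make_process_traces].
#' @param config a [simulation_config].
#' @return list with `marker` and `signal` ([channel_image]s) and `truth`
#'   (data.frame: `x_um, y_um, area_um2, amp_marker, amp_signal,
#'   mean_marker_true, mean_signal_true, type, on_process, process_id`).
#' @export
render_image_pair <- function(traces, config) {
  if (config$psf_sigma <= 0) stop("psf_sigma must be > 0")
  if (config$distractor_rate < 0 || config$speckle_rate < 0) {
    stop("spot rates must be >= 0")
  }
  shape <- config$image_shape
  ps <- config$pixel_size
  xmax <- shape[2] * ps
  ymax <- shape[1] * ps

  with_seed(config$seed + 1000003L, {
    # --- spot geometry (independent of condition_factor) ---
    pos <- list()
    for (i in seq_along(traces$polylines)) {
      L <- traces$lengths[i]
      n_i <- stats::rpois(1, config$puncta_per_micron * L)
      if (n_i > 0) {
        s <- sort(stats::runif(n_i, 0, L))
        xy <- point_at_arclength(traces$polylines[[i]], s)
        pos[[length(pos) + 1]] <- data.frame(
          x_um = xy[, 1], y_um = xy[, 2], type = "punctum",
          on_process = TRUE, process_id = i
        )
      }
    }
    n_dis <- stats::rpois(1, config$distractor_rate)
    if (n_dis > 0) {
      dx <- dy <- numeric(0)
      tries <- 0L
      while (length(dx) < n_dis && tries < 2000L * n_dis) {
        tries <- tries + 1L
        px <- stats::runif(1, 0.5, xmax - 0.5)
        py <- stats::runif(1, 0.5, ymax - 0.5)
        d <- dist_points_traces(cbind(px, py), traces)$distance
        if (d > config$distractor_min_distance) {
          dx <- c(dx, px)
          dy <- c(dy, py)
        }
      }
      if (length(dx) > 0) {
        pos[[length(pos) + 1]] <- data.frame(
          x_um = dx, y_um = dy, type = "distractor",
          on_process = FALSE, process_id = NA_integer_
        )
      }
    }
    n_spk <- stats::rpois(1, config$speckle_rate)
    if (n_spk > 0) {
      pos[[length(pos) + 1]] <- data.frame(
        x_um = stats::runif(n_spk, 0.5, xmax - 0.5),
        y_um = stats::runif(n_spk, 0.5, ymax - 0.5),
        type = "speckle", on_process = FALSE, process_id = NA_integer_
      )
    }
    truth <- if (length(pos)) do.call(rbind, pos) else
      data.frame(x_um = numeric(0), y_um = numeric(0), type = character(0),
                 on_process = logical(0), process_id = integer(0))

    n_spot <- nrow(truth)
    amp_m <- .sample_amplitudes(n_spot, config$marker_intensity_dist,
                                config$amplitude_truncation)
    amp_s <- .sample_amplitudes(n_spot, config$signal_intensity_dist,
                                config$amplitude_truncation)
    amp_s <- amp_s * config$condition_factor

    sigma <- ifelse(truth$type == "speckle", config$speckle_sigma,
                    config$psf_sigma)
    marker_px <- matrix(0, shape[1], shape[2])
    signal_px <- matrix(0, shape[1], shape[2])
    for (k in seq_len(n_spot)) {
      marker_px <- .add_spot(marker_px, truth$x_um[k], truth$y_um[k],
                             amp_m[k], sigma[k], ps)
      signal_px <- .add_spot(signal_px, truth$x_um[k], truth$y_um[k],
                             amp_s[k], sigma[k], ps)
    }

    if (config$background_sigma > 0) {
      marker_px <- marker_px +
        matrix(stats::rnorm(length(marker_px), 0, config$background_sigma),
               shape[1], shape[2])
      signal_px <- signal_px +
        matrix(stats::rnorm(length(signal_px), 0, config$background_sigma),
               shape[1], shape[2])
      marker_px[marker_px < 0] <- 0
      signal_px[signal_px < 0] <- 0
    }

    # true area: the above-half-maximum disk of the Gaussian spot
    half_area <- pi * (sigma * sqrt(2 * log(2)))^2
    truth$area_um2 <- half_area
    truth$amp_marker <- amp_m
    truth$amp_signal <- amp_s
    # mean pre-noise intensity over the half-maximum disk: amp / (2 ln 2)
    truth$mean_marker_true <- amp_m / (2 * log(2))
    truth$mean_signal_true <- amp_s / (2 * log(2))
    truth <- truth[, c("x_um", "y_um", "area_um2", "amp_marker", "amp_signal",
                       "mean_marker_true", "mean_signal_true", "type",
                       "on_process", "process_id")]
    rownames(truth) <- NULL

    list(
      marker = channel_image(marker_px, ps, "synaptophysin"),
      signal = channel_image(signal_px, ps, "SNAP29"),
      truth = truth
    )
  })
}

#' Generate a multi-condition synthetic experiment on disk
#'
#' Writes, per condition and image: the two channel TIFFs
#' (`*_marker.tif`, `*_signal.tif`), a polyline trace CSV and a
#' ground-truth CSV, plus one YAML manifest recording per-image seeds and
#' the full per-condition configuration, so [replay_manifest] reproduces
#' every file byte-for-byte.
#'
#' @param configs named list of [simulation_config]s, one per condition;
#'   each image of a condition uses `config$seed + image_index - 1`.
#' @param n_images_per_condition images per condition.
#' @param out_dir output directory (created if needed).
#' @return path to the written `manifest.yaml` (invisibly).
#' @export
generate_experiment <- function(configs, n_images_per_condition, out_dir) {
  if (length(configs) < 1 || is.null(names(configs)) ||
      any(names(configs) == "")) {
    stop("configs must be a non-empty named list of simulation_config objects")
  }
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir)
  }
  manifest <- list(images = list(), configs = list())
  for (cond in names(configs)) {
    cfg <- configs[[cond]]
    manifest$configs[[cond]] <- unclass(cfg)
    for (i in seq_len(n_images_per_condition)) {
      cfg_i <- cfg
      cfg_i$seed <- cfg$seed + i - 1L
      stem <- sprintf("%s_%02d", gsub("[^A-Za-z0-9_.-]", "_", cond), i)
      traces <- make_process_traces(cfg_i)
      im <- render_image_pair(traces, cfg_i)
      paths <- list(
        marker = file.path(out_dir, paste0(stem, "_marker.tif")),
        signal = file.path(out_dir, paste0(stem, "_signal.tif")),
        traces = file.path(out_dir, paste0(stem, "_traces.csv")),
        truth = file.path(out_dir, paste0(stem, "_truth.csv"))
      )
      write_channel_image(im$marker, paths$marker)
      write_channel_image(im$signal, paths$signal)
      write_traces(traces, paths$traces)
      utils::write.csv(im$truth, paths$truth, row.names = FALSE, quote = FALSE)
      manifest$images[[length(manifest$images) + 1]] <- list(
        image_id = stem, condition = cond, seed = cfg_i$seed,
        pixel_size = cfg$pixel_size,
        marker = basename(paths$marker), signal = basename(paths$signal),
        traces = basename(paths$traces), truth = basename(paths$truth)
      )
    }
  }
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path, precision = 15)
  invisible(manifest_path)
}

#' Regenerate a synthetic experiment from its manifest
#'
#' @param manifest_path path to a `manifest.yaml` written by
#'   [generate_experiment].
#' @param out_dir output directory.
#' @return path to the regenerated manifest (invisibly).
#' @export
replay_manifest <- function(manifest_path, out_dir) {
  man <- yaml::read_yaml(manifest_path)
  n_per <- length(man$images) / length(man$configs)
  configs <- lapply(man$configs, function(cf) {
    cf$image_shape <- as.integer(cf$image_shape)
    do.call(simulation_config, cf)
  })
  generate_experiment(configs, n_per, out_dir)
}
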