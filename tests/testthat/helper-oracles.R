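# Independent oracles and fixture builders. Everything here is written
# from first principles, separately from the package internals, so tests
# compare two independent routes to the same quantity.

# --- flood-fill connected-component labeling (8-connectivity) ----------
# Labels are assigned in raster-scan (row-major) order of each component's
# first pixel, matching the package's documented numbering.
flood_fill_labels <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  next_label <- 0L
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (!mask[r, c] || lab[r, c] != 0L) next
      next_label <- next_label + 1L
      stack <- list(c(r, c))
      lab[r, c] <- next_label
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1] + dr
          cc <- p[2] + dc
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              mask[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- next_label
            stack[[length(stack) + 1]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

# --- brute-force point-to-polyline distance ----------------------------
brute_point_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((p - a)^2)))
  t <- sum((p - a) * ab) / len2
  t <- min(1, max(0, t))
  sqrt(sum((p - (a + t * ab))^2))
}

brute_component_distance <- function(pixels, polylines, pixel_size) {
  best <- Inf
  for (k in seq_len(nrow(pixels))) {
    p <- c((pixels[k, 2] - 0.5) * pixel_size, (pixels[k, 1] - 0.5) * pixel_size)
    for (poly in polylines) {
      for (i in seq_len(nrow(poly) - 1)) {
        d <- brute_point_segment(p, poly[i, ], poly[i + 1, ])
        if (d < best) best <- d
      }
    }
  }
  best
}

# --- brute-force two-sample K-S statistic ------------------------------
brute_ks_D <- function(x, y) {
  pooled <- c(x, y)
  max(vapply(pooled, function(v) abs(mean(x <= v) - mean(y <= v)), numeric(1)))
}

# Kolmogorov tail probability by the theta-function (dual) series:
# Q(lambda) = 1 - sqrt(2*pi)/lambda * sum_k exp(-(2k-1)^2 pi^2 / (8 lambda^2))
theta_kolmogorov_q <- function(lambda) {
  if (lambda <= 0) return(1)
  s <- 0
  for (k in 1:200) {
    term <- exp(-(2 * k - 1)^2 * pi^2 / (8 * lambda^2))
    s <- s + term
    if (term < 1e-18) break
  }
  1 - sqrt(2 * pi) / lambda * s
}

# --- independent Gaussian-spot renderer for constructed fixtures -------
paint_spot <- function(px, x_um, y_um, amp, sigma_um, pixel_size) {
  nr <- nrow(px)
  nc <- ncol(px)
  for (r in seq_len(nr)) {
    cy <- (r - 0.5) * pixel_size
    if (abs(cy - y_um) > 5 * sigma_um) next
    for (c in seq_len(nc)) {
      cx <- (c - 0.5) * pixel_size
      d2 <- (cx - x_um)^2 + (cy - y_um)^2
      if (d2 <= (5 * sigma_um)^2) {
        px[r, c] <- px[r, c] + amp * exp(-d2 / (2 * sigma_um^2))
      }
    }
  }
  px
}

# horizontal straight-line trace at height y_um spanning [x0, x1]
straight_trace <- function(y_um, x0, x1, pixel_size, image_shape) {
  process_traces(list(cbind(x = c(x0, x1), y = c(y_um, y_um))),
                 pixel_size, image_shape)
}

# minimal punctum table wrapper for pixel-set operations
table_with_pixels <- function(pixel_sets, pixel_size) {
  n <- length(pixel_sets)
  tab <- data.frame(punctum_id = seq_len(n))
  attr(tab, "pixels") <- pixel_sets
  attr(tab, "pixel_size") <- pixel_size
  tab
}

# brute-force all-pairs overlap enumeration for colocalization
brute_overlap_pairs <- function(sp, mp) {
  out <- data.frame(signal_id = integer(0), marker_id = integer(0),
                    overlap_px = integer(0))
  for (i in seq_along(sp)) {
    best_j <- 0L
    best_ov <- 0L
    for (j in seq_along(mp)) {
      a <- paste(sp[[i]][, 1], sp[[i]][, 2])
      b <- paste(mp[[j]][, 1], mp[[j]][, 2])
      ov <- length(intersect(a, b))
      if (ov > best_ov) {
        best_ov <- ov
        best_j <- j
      }
    }
    if (best_ov > 0) {
      out <- rbind(out, data.frame(signal_id = i, marker_id = best_j,
                                   overlap_px = best_ov))
    }
  }
  out
}

# random binary mask for labeling oracle tests
random_mask <- function(nr, nc, p_fg) {
  matrix(stats::runif(nr * nc) < p_fg, nr, nc)
}

# detection parameters used throughout the packaged synthetic study:
# fixed global threshold at 25/255 (about 2 sd of the default background
# noise after normalization), everything else at the published defaults
study_params <- function() {
  detection_params(threshold_mode = "fixed", fixed_threshold = 25)
}
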