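ps <- 0.1

test_that("normalization maps linearly onto [0, 255]", {
  img <- channel_image(matrix(c(10, 15, 20, 12), 2, 2), ps)
  n <- normalize_image(img)
  expect_equal(n$pixels[1, 1], 0)
  expect_equal(n$pixels[1, 2], 255)
  expect_equal(n$pixels[2, 1], 127.5)
  # constant input maps to all zeros
  flat <- normalize_image(channel_image(matrix(7, 3, 3), ps))
  expect_true(all(flat$pixels == 0))
  # idempotence
  expect_equal(normalize_image(n)$pixels, n$pixels)
  # original untouched
  expect_equal(img$pixels[1, 1], 10)
})

test_that("binarization thresholds strictly and validates its inputs", {
  zero <- channel_image(matrix(0, 8, 8), ps)
  expect_true(all(!binarize(zero, detection_params(
    threshold_mode = "fixed", fixed_threshold = 0))))
  two <- channel_image(matrix(c(50, 150, 50, 150), 2, 2), ps)
  m <- binarize(normalize_image(two), detection_params(
    threshold_mode = "fixed", fixed_threshold = 100))
  expect_equal(m, two$pixels == 150, ignore_attr = TRUE)
  expect_error(detection_params(threshold_mode = "fixed",
                                fixed_threshold = 300), "\\[0, 255\\]")
  expect_error(binarize(channel_image(matrix(c(-5, 300, 0, 0), 2, 2), ps)),
               "normalized")
})

test_that("auto threshold maximizes inter-class variance (brute-force oracle)", {
  set.seed(42)
  v <- c(pmin(pmax(rnorm(3000, 30, 10), 0), 255),
         pmin(pmax(rnorm(1000, 200, 15), 0), 255))
  px <- matrix(v, 50, 80)
  thr <- otsu_threshold(px)
  expect_gt(thr, 60)   # strictly between the two modes
  expect_lt(thr, 170)
  # brute force over all 256 candidate thresholds on the binned histogram
  b <- floor(pmin(pmax(px, 0), 255))
  bcv <- vapply(0:254, function(t) {
    lo <- b[b <= t]
    hi <- b[b > t]
    if (length(lo) == 0 || length(hi) == 0) return(-Inf)
    w0 <- length(lo) / length(b)
    w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  expect_equal(thr, (0:254)[which.max(bcv)])
  # EBImage's Otsu also lands in the inter-mode gap (the criterion is
  # nearly flat across the valley, so exact agreement is not expected)
  if (requireNamespace("EBImage", quietly = TRUE)) {
    eb <- EBImage::otsu(EBImage::Image(t(px) / 255), range = c(0, 1)) * 255
    expect_gt(eb, 60)
    expect_lt(eb, 170)
  }
})

test_that("diagonally touching pixels form one 8-connected object", {
  m <- matrix(0, 5, 5)
  m[2, 2] <- 1
  m[3, 3] <- 1
  expect_equal(label_components(m)$n, 1)
  m2 <- matrix(0, 5, 5)
  m2[2, 2] <- 1
  m2[2, 4] <- 1  # separated by one background pixel
  expect_equal(label_components(m2)$n, 2)
})

test_that("component labels match an independent flood-fill oracle", {
  set.seed(7)
  for (i in 1:30) {
    m <- random_mask(32, 32, runif(1, 0.2, 0.6))
    got <- label_components(m)
    expect_identical(got$labels, flood_fill_labels(m))
    expect_equal(got$n, max(flood_fill_labels(m)))
  }
})

test_that("component-to-process distances are exact", {
  shape <- c(64L, 64L)
  tr <- straight_trace(0.05, 0.5, 5.5, ps, shape)
  # component centred on the polyline -> distance 0
  on_line <- cbind(row = 1L, col = 20L)  # centre (1.95, 0.05)
  expect_equal(component_distance(on_line, tr, ps)$distance_um, 0)
  # single pixel centre 1.5 um from the line
  off <- cbind(row = 16L, col = 20L)     # centre y = 1.55
  expect_equal(component_distance(off, tr, ps)$distance_um, 1.5)
  # empty traces -> infinite distance, no process id
  none <- process_traces(list(), ps, shape)
  d <- component_distance(off, none, ps)
  expect_equal(d$distance_um, Inf)
  expect_true(is.na(d$process_id))
  expect_error(component_distance(cbind(row = integer(0), col = integer(0)),
                                  tr, ps), "empty")
})

test_that("distances match a brute-force pixel-by-segment scan", {
  set.seed(11)
  for (i in 1:50) {
    npx <- sample(1:30, 1)
    pix <- cbind(row = sample(1:64, npx, replace = TRUE),
                 col = sample(1:64, npx, replace = TRUE))
    polys <- lapply(seq_len(sample(1:3, 1)), function(j) {
      nv <- sample(2:5, 1)
      cbind(x = runif(nv, 0, 6.4), y = runif(nv, 0, 6.4))
    })
    tr <- process_traces(polys, ps, c(64L, 64L))
    got <- component_distance(pix, tr, ps)$distance_um
    expect_equal(got, brute_component_distance(pix, polys, ps),
                 tolerance = 1e-9)
  }
})

make_fixture <- function() {
  # noiseless constructed scene: 10 well-separated on-process spots with
  # areas in the analysis window, 2 distractors far from the process,
  # 5 sub-threshold speckles
  shape <- c(200L, 520L)
  tr <- straight_trace(5, 2, 50, ps, shape)
  px <- matrix(0, shape[1], shape[2])
  spot_x <- seq(4, 49, length.out = 10)
  for (x in spot_x) px <- paint_spot(px, x, 5, 200, 0.3, ps)
  for (x in c(10, 30)) px <- paint_spot(px, x, 15, 200, 0.3, ps)  # 10 um away
  for (x in spot_x[1:5] + 2.5) {
    px <- paint_spot(px, x, 5, 150, 0.09, ps)   # on-trace sub-area speckles
  }
  sig <- 0.5 * px
  list(marker = channel_image(px, ps), signal = channel_image(sig, ps),
       traces = tr, spot_x = spot_x, shape = shape)
}

test_that("the detector keeps exactly the true on-process spots", {
  fx <- make_fixture()
  tab <- detect_puncta(fx$marker, fx$signal, fx$traces, study_params(),
                       image_id = "fixture")
  expect_equal(nrow(tab), 10)
  log <- attr(tab, "log")
  expect_equal(log$removed_distance, 2)
  expect_equal(log$removed_small_area, 5)
  # 1:1 nearest-centroid match against the constructed truth
  matched <- vapply(fx$spot_x, function(x) {
    which.min(abs(tab$centroid_x_um - x))
  }, integer(1))
  expect_equal(sort(matched), 1:10)
  expect_true(all(abs(sort(tab$centroid_x_um) - fx$spot_x) < 0.1))
  # signal channel is half the marker everywhere -> ratio 0.5 per punctum
  expect_equal(tab$signal_over_marker, rep(0.5, 10), tolerance = 1e-9)
  expect_true(all(tab$area_um2 >= 0.35 & tab$area_um2 <= 10))
  expect_true(all(tab$distance_um <= 1))
})

test_that("foreground area is conserved across keep/remove partitioning", {
  fx <- make_fixture()
  norm <- normalize_image(fx$marker)
  mask <- binarize(norm, study_params())
  total_area <- sum(mask) * ps^2
  lab <- label_components(mask)
  all_areas <- vapply(lab$pixels, nrow, integer(1)) * ps^2
  tab <- detect_puncta(fx$marker, fx$signal, fx$traces, study_params())
  expect_equal(sum(all_areas), total_area)
  removed_area <- sum(all_areas) - sum(tab$area_um2)
  expect_equal(sum(tab$area_um2) + removed_area, total_area)
  expect_equal(attr(tab, "log")$n_components, lab$n)
})

test_that("widening any filter never loses puncta (monotonicity)", {
  cfg <- simulation_config(seed = 21L, image_shape = c(256L, 256L))
  tr <- make_process_traces(cfg)
  im <- render_image_pair(tr, cfg)
  base <- detect_puncta(im$marker, im$signal, tr, study_params())
  wider_area <- detect_puncta(im$marker, im$signal, tr, detection_params(
    threshold_mode = "fixed", fixed_threshold = 25,
    min_area = 0.1, max_area = 20))
  wider_dist <- detect_puncta(im$marker, im$signal, tr, detection_params(
    threshold_mode = "fixed", fixed_threshold = 25, max_distance = 3))
  expect_gte(nrow(wider_area), nrow(base))
  expect_gte(nrow(wider_dist), nrow(base))
})

test_that("shape or calibration mismatches are rejected", {
  a <- channel_image(matrix(0, 8, 8), ps)
  b <- channel_image(matrix(0, 8, 9), ps)
  c2 <- channel_image(matrix(0, 8, 8), 0.2)
  tr <- process_traces(list(), ps, c(8L, 8L))
  expect_error(detect_puncta(a, b, tr), "shape")
  expect_error(detect_puncta(a, c2, tr), "calibration")
})
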