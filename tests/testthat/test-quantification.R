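ps <- 0.1

fake_table <- function(n, process_id = 1L) {
  data.frame(
    punctum_id = seq_len(n), image_id = rep("img", n),
    centroid_x_um = seq_len(n), centroid_y_um = rep(1, n),
    area_um2 = rep(1, n), distance_um = rep(0, n),
    process_id = rep(process_id, n),
    mean_marker = rep(100, n), mean_signal = rep(50, n),
    signal_over_marker = rep(0.5, n)
  )
}

test_that("density per micron divides counts by process length", {
  tr <- straight_trace(3, 1, 21, ps, c(64L, 256L))  # 20 um
  d <- density_per_micron(fake_table(10), tr)
  expect_equal(d$per_image, 0.5)
  expect_equal(d$per_process$rate, 0.5)
  expect_equal(density_per_micron(fake_table(0), tr)$per_image, 0)
  none <- process_traces(list(), ps, c(64L, 64L))
  expect_error(density_per_micron(fake_table(1), none), "traces")
})

test_that("simulated density is recovered across seeds", {
  # 20 um process at 0.5 puncta/um, sparse enough that merging is rare
  shape <- c(60L, 220L)
  tr <- straight_trace(3, 1, 21, ps, shape)
  params <- study_params()
  rates <- vapply(1:30, function(s) {
    cfg <- simulation_config(image_shape = shape, n_processes = 1L,
                             puncta_per_micron = 0.25, distractor_rate = 0,
                             speckle_rate = 0, seed = 400L + s)
    im <- render_image_pair(tr, cfg)
    tab <- detect_puncta(im$marker, im$signal, tr, params)
    density_per_micron(tab, tr)$per_image
  }, numeric(1))
  # Poisson placement merges neighbours closer than the spot diameter
  # (~1.3 um at these amplitudes) into one component, thinning the
  # detected rate to about lambda * exp(-lambda * delta); the measured
  # density must fall between that floor and the placement rate
  se <- sqrt(0.25 / 20 / 30)
  expect_gt(mean(rates), 0.25 * exp(-0.25 * 1.5) - 3 * se)
  expect_lte(mean(rates), 0.25 + 3 * se)
})

test_that("colocalization pairs match exhaustive overlap enumeration", {
  sq <- function(r0, c0, k) as.matrix(expand.grid(row = r0:(r0 + k - 1),
                                                  col = c0:(c0 + k - 1)))
  # identical pixel sets -> one pair
  a <- table_with_pixels(list(sq(5, 5, 3)), ps)
  b <- table_with_pixels(list(sq(5, 5, 3)), ps)
  expect_equal(colocalize(a, b)$n_colocalized, 1)
  # disjoint sets -> none
  c2 <- table_with_pixels(list(sq(20, 20, 3)), ps)
  expect_equal(colocalize(a, c2)$n_colocalized, 0)

  # 6 signal vs 5 marker puncta with partial, nested, and tied overlaps
  sp <- list(sq(1, 1, 3), sq(10, 10, 2), sq(20, 20, 4), sq(30, 30, 2),
             sq(40, 40, 3), sq(50, 50, 2))
  mp <- list(sq(2, 2, 3), sq(10, 10, 2), sq(21, 21, 2), sq(28, 28, 3),
             sq(60, 60, 2))
  s_tab <- table_with_pixels(sp, ps)
  m_tab <- table_with_pixels(mp, ps)
  got <- colocalize(s_tab, m_tab)$pairs
  want <- brute_overlap_pairs(sp, mp)
  expect_equal(got$signal_id, want$signal_id)
  expect_equal(got$marker_id, want$marker_id)
  expect_equal(got$overlap_px, want$overlap_px)

  tr <- straight_trace(3, 1, 21, ps, c(64L, 256L))
  expect_equal(colocalize(s_tab, m_tab, tr)$coloc_per_micron,
               nrow(want) / 20)
  # coloc density cannot exceed either channel's punctum density
  expect_lte(colocalize(s_tab, m_tab, tr)$coloc_per_micron,
             min(length(sp), length(mp)) / 20)
})

test_that("marker-normalized ratios behave at the edges", {
  tab <- fake_table(4)
  expect_equal(signal_over_marker(tab)$ratio, rep(0.5, 4))
  tab$mean_signal <- tab$mean_marker
  expect_equal(signal_over_marker(tab)$mean, 1)
  tab$mean_signal <- 0
  expect_equal(signal_over_marker(tab)$ratio, rep(0, 4))
  tab$mean_marker[1] <- 0
  r <- signal_over_marker(tab)
  expect_equal(r$n_excluded, 1)
  expect_equal(r$n, 3)
})

uniform_profile <- function(intensity = 10, punctum_ids = c(0, 0, 1, 1, 0, 0)) {
  data.frame(process_id = 1L, s_um = seq_along(punctum_ids) * 0.05,
             x_um = 0, y_um = 0,
             intensity = rep(intensity, length(punctum_ids)),
             punctum_id = punctum_ids)
}

test_that("accumulation index reproduces the defining cases", {
  # uniform intensity -> AI = 0.5
  ai <- accumulation_index(uniform_profile())
  expect_equal(ai$ai, 0.5)
  # zero shaft, positive punctum -> AI = 1
  pr <- uniform_profile()
  pr$intensity <- ifelse(pr$punctum_id > 0, 40, 0)
  expect_equal(accumulation_index(pr)$ai, 1)
  # piecewise 80 (punctum) / 20 (shaft) -> AI = 0.8
  pr2 <- uniform_profile()
  pr2$intensity <- ifelse(pr2$punctum_id > 0, 80, 20)
  expect_equal(accumulation_index(pr2)$ai, 0.8)
  # all-punctum process -> flagged, no shaft
  pr3 <- uniform_profile(punctum_ids = c(1, 1, 1))
  a3 <- accumulation_index(pr3)
  expect_true(is.na(a3$ai))
  expect_equal(a3$flag, "no_shaft")
  # zero everywhere -> flagged undefined
  pr4 <- uniform_profile(intensity = 0)
  expect_equal(accumulation_index(pr4)$flag, "zero_signal")
})

test_that("accumulation index is scale-invariant and monotone", {
  pr <- uniform_profile()
  pr$intensity <- c(10, 12, 50, 60, 11, 9)
  base <- accumulation_index(pr)$ai
  pr_scaled <- pr
  pr_scaled$intensity <- pr$intensity * 7.3
  expect_equal(accumulation_index(pr_scaled)$ai, base, tolerance = 1e-12)
  pr_brighter <- pr
  pr_brighter$intensity[pr$punctum_id > 0] <- c(80, 90)
  expect_gt(accumulation_index(pr_brighter)$ai, base)
})

test_that("profiles sample the signal along the trace with punctum flags", {
  shape <- c(64L, 256L)
  tr <- straight_trace(3, 1, 21, ps, shape)
  sig <- channel_image(matrix(13, shape[1], shape[2]), ps)
  # one punctum occupying columns 100..110 around the trace row
  pixset <- as.matrix(expand.grid(row = 28:33, col = 100:110))
  colnames(pixset) <- c("row", "col")
  tab <- fake_table(1)
  attr(tab, "pixels") <- list(pixset)
  attr(tab, "pixel_size") <- ps
  pr <- accumulation_profile(tr, sig, tab)
  expect_equal(unique(pr$intensity), 13)
  expect_setequal(unique(pr$punctum_id), c(0L, 1L))
  expect_true(all(diff(pr$s_um) > 0))
  expect_true(all(pr$s_um >= 0 & pr$s_um <= 20 + 1e-9))
  # uniform image -> AI exactly 0.5
  expect_equal(accumulation_index(pr)$ai, 0.5)
})

test_that("image summaries aggregate hand-computable statistics", {
  tr <- straight_trace(3, 1, 21, ps, c(64L, 256L))
  tab <- fake_table(5)
  tab$mean_signal <- c(10, 20, 30, 40, 50)
  tab$signal_over_marker <- tab$mean_signal / tab$mean_marker
  s <- summarize_image(tab, tr, image_id = "i1", condition = "WT")
  expect_equal(s$n_puncta, 5)
  expect_equal(s$puncta_per_micron, 0.25)
  expect_equal(s$mean_signal_mean, 30)
  expect_equal(s$mean_signal_sem, sd(c(10, 20, 30, 40, 50)) / sqrt(5))
  expect_equal(s$ratio_mean, 0.3)
  # empty table -> zero counts, flagged (NA) means, no error
  s0 <- summarize_image(fake_table(0), tr)
  expect_equal(s0$n_puncta, 0)
  expect_equal(s0$puncta_per_micron, 0)
  expect_true(is.na(s0$mean_signal_mean))
  # single punctum -> SEM undefined
  s1 <- summarize_image(fake_table(1), tr)
  expect_true(is.na(s1$mean_signal_sem))
})
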