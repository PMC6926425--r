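test_that("non-touching synthetic nuclei are recovered with accurate centroids", {
  sim <- simulate_image(n_nuclei = 12, seed = 21, noise_sd = 10)
  seg <- segment_nuclei(sim$field)
  expect_equal(nrow(seg$objects), 12)
  expect_true(all(truth_centroid_errors(seg, sim$truth) <= 2))
  # labels contiguous 1..K and table consistent with the label map
  expect_identical(sort(unique(as.integer(seg$label_map[seg$label_map > 0]))),
                   seq_len(12))
})

test_that("watershed splits touching disk pairs into plausible halves", {
  sim <- simulate_image(n_nuclei = 8, touching_fraction = 0.5, seed = 13,
                        radius_sd = 0.5)
  seg <- segment_nuclei(sim$field)
  expect_equal(nrow(seg$objects), 8)
  idx <- match_truth_objects(seg, sim$truth)
  expect_equal(length(unique(idx)), 8)  # one object per truth nucleus
  for (k in which(sim$truth$touching)) {
    expected <- pi * sim$truth$radius[k]^2
    expect_lt(abs(seg$objects$area_px[idx[k]] - expected) / expected, 0.15)
  }
})

test_that("degenerate images raise a no-foreground error", {
  blank <- image_field(matrix(0, 64, 64))
  expect_error(segment_nuclei(blank), "no foreground")
  flat <- image_field(matrix(100, 64, 64))
  expect_error(segment_nuclei(flat), "no foreground")
})

test_that("per-object intensities are exact on painted objects", {
  nuc <- matrix(0, 80, 80)
  nuc[10:25, 10:25] <- 300      # object 1
  nuc[50:70, 40:60] <- 300      # object 2
  sig <- matrix(0, 80, 80)
  sig[10:25, 10:25] <- 100
  sig[50:70, 40:60] <- 900
  f <- image_field(nuc, sig)
  seg <- segment_nuclei(f, smooth_radius = 0, min_area_px = 10)
  expect_equal(nrow(seg$objects), 2)
  means <- measure_nuclear_intensity(seg, "signal")
  expect_equal(sort(unname(means)), c(100, 900))
  # intensity additivity: total = mean x area
  expect_equal(seg$objects$total_signal,
               seg$objects$mean_signal * seg$objects$area_px)
  # label conservation: areas sum to the labelled pixel count
  expect_equal(sum(seg$objects$area_px), sum(seg$label_map > 0))
})

test_that("areas match disk geometry and convert to microns", {
  nuc <- matrix(0, 64, 64)
  d <- sqrt(outer((1:64 - 32)^2, (1:64 - 32)^2, `+`))
  nuc[d <= 10] <- 500
  f <- image_field(nuc, pixel_size = 0.5)
  seg <- segment_nuclei(f, smooth_radius = 0)
  a <- measure_nuclear_area(seg)
  expect_equal(nrow(a), 1)
  expect_lt(abs(a$area_px - pi * 100) / (pi * 100), 0.05)
  expect_equal(a$area_um2, a$area_px * 0.25)
})

test_that("segmentation is invariant to affine intensity rescaling", {
  sim <- simulate_image(n_nuclei = 10, seed = 31, noise_sd = 8)
  seg1 <- segment_nuclei(sim$field)
  f2 <- image_field(sim$field$nuclear * 3.7 + 50, sim$field$signal)
  seg2 <- segment_nuclei(f2)
  expect_identical(seg1$label_map, seg2$label_map)
})

test_that("non-touching fields agree with a connected-components oracle", {
  sim <- simulate_image(n_nuclei = 12, seed = 77)
  # oracle: plain connected components on a truth-informed fixed threshold,
  # no filtering, no watershed
  cc <- EBImage::bwlabel(EBImage::Image(sim$field$nuclear > 250))
  cc <- matrix(as.integer(EBImage::imageData(cc)), nrow = 256)
  seg <- segment_nuclei(sim$field)
  expect_equal(nrow(seg$objects), max(cc))
  for (l in seq_len(max(cc))) {
    idx <- which(cc == l)
    r <- mean((idx - 1) %% 256 + 1)
    c <- mean((idx - 1) %/% 256 + 1)
    expect_lt(min(sqrt((seg$objects$centroid_r - r)^2 +
                         (seg$objects$centroid_c - c)^2)), 2)
  }
})

test_that("object QC filter excludes border and bright objects, else identity", {
  sim <- simulate_image(n_nuclei = 10, seed = 41)
  seg <- segment_nuclei(sim$field)

  noop <- object_qc_filter(seg)
  expect_identical(noop$seg$objects, seg$objects)
  expect_equal(nrow(noop$excluded), 0)

  # inject 3 mitotic-like blobs far brighter than any nucleus
  nuc <- sim$field$nuclear
  put_blob <- function(m, r, c) {
    m[(r - 4):(r + 4), (c - 4):(c + 4)] <- 2000
    m
  }
  spots <- list(c(15, 240), c(240, 15), c(240, 240))
  for (s in spots) nuc <- put_blob(nuc, s[1], s[2])
  f2 <- image_field(nuc, sim$field$signal)
  seg2 <- segment_nuclei(f2, min_area_px = 30)
  flt <- object_qc_filter(seg2, field = f2, max_intensity_percentile = 0.99)
  expect_equal(nrow(flt$excluded), 3)
  expect_true(all(flt$excluded$reason == "bright"))
  expect_equal(nrow(flt$seg$objects), nrow(seg2$objects) - 3)

  # border rule: pad an object onto the border, then exclude it
  nuc3 <- sim$field$nuclear
  nuc3[1:12, 100:120] <- 500
  f3 <- image_field(nuc3, sim$field$signal)
  seg3 <- segment_nuclei(f3)           # border objects already discarded
  seg3$label_map[1:12, 100:120] <- max(seg3$label_map) + 1L
  seg3$objects <- rbind(seg3$objects, seg3$objects[1, ])
  seg3$objects$label[nrow(seg3$objects)] <- max(seg3$label_map)
  flt3 <- object_qc_filter(seg3, border_exclusion = TRUE)
  expect_true(any(flt3$excluded$reason == "border"))
})

test_that("label maps round-trip through 16-bit TIFF", {
  sim <- simulate_image(n_nuclei = 6, seed = 55)
  seg <- segment_nuclei(sim$field)
  path <- withr::local_tempfile(fileext = ".tif")
  write_label_map(seg$label_map, path)
  expect_identical(read_label_map(path), seg$label_map)
})
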