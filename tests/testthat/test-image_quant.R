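blank_stack <- function(side = 40, extra = c("tag", "cd45", "marker")) {
  ch <- c(list(nuclear = matrix(0.01, side, side)),
          setNames(lapply(extra, function(x) matrix(0.01, side, side)), extra))
  image_stack(ch)
}

test_that("image stacks validate shapes and intensities", {
  expect_error(image_stack(list(matrix(0, 2, 2))), "named")
  expect_error(image_stack(list(nuclear = matrix(0, 2, 2),
                                tag = matrix(0, 3, 3))), "identical")
  expect_error(image_stack(list(nuclear = matrix(-1, 2, 2))), "non-negative")
})

test_that("segmentation finds disks, drops small ones, needs a nuclear channel", {
  expect_equal(max(segment_nuclei(blank_stack())), 0)

  sim <- simulate_if_image(n_ctc = 3, n_immune = 2, frac_marker_positive = 1,
                           seed = 5)
  labels <- segment_nuclei(sim$stack, segmentation_config(min_area = 10))
  expect_equal(max(labels), 5)

  # an object of area min_area - 1 is discarded, at min_area kept
  st <- blank_stack(side = 20)
  st$channels$nuclear[5:8, 5:8] <- 0.9   # 16 px
  expect_equal(max(segment_nuclei(st, segmentation_config(min_area = 17))), 0)
  expect_equal(max(segment_nuclei(st, segmentation_config(min_area = 16))), 1)

  expect_error(segment_nuclei(image_stack(list(tag = matrix(1, 4, 4)))),
               "nuclear")
})

test_that("component labeling matches a flood-fill oracle at 4 and 8", {
  diag2 <- matrix(0, 5, 5); diag2[2, 2] <- 1; diag2[3, 3] <- 1
  expect_equal(max(ctcscreen:::label_components(diag2, 4)), 2)
  expect_equal(max(ctcscreen:::label_components(diag2, 8)), 1)
  set.seed(3)
  for (i in 1:15) {
    mask <- matrix(rbinom(15 * 12, 1, 0.4), nrow = 15)
    for (conn in c(4, 8)) {
      got <- canonical_labels(ctcscreen:::label_components(mask, conn))
      want <- canonical_labels(oracle_label(mask, conn))
      expect_identical(got, want)
    }
  }
})

test_that("mean gray values are exact per object and channel", {
  labels <- matrix(0L, 4, 4)
  labels[1, 1] <- 1L; labels[1, 2] <- 1L
  labels[3, 3] <- 2L
  ch <- matrix(0, 4, 4); ch[1, 1] <- 0.1; ch[1, 2] <- 0.2; ch[3, 3] <- 0.7
  uni <- matrix(0.7, 4, 4)
  st <- image_stack(list(nuclear = uni, marker = ch))
  meas <- measure_cells(labels, st)
  expect_equal(meas$marker, c(0.15, 0.7))
  expect_equal(meas$nuclear, c(0.7, 0.7))
  expect_equal(meas$area, c(2L, 1L))
  expect_equal(meas$centroid_row, c(1, 3))
  expect_equal(meas$centroid_col, c(1.5, 3))

  empty <- measure_cells(matrix(0L, 4, 4), st)
  expect_equal(nrow(empty), 0)
  expect_error(measure_cells(matrix(0L, 3, 3), st), "shape")
})

test_that("classification applies the tag/CD45 rules with ambiguity excluded", {
  meas <- data.frame(label = 1:4, area = 30, centroid_row = 1, centroid_col = 1,
                     tag = c(0.9, 0.1, 0.9, 0.1),
                     cd45 = c(0.1, 0.9, 0.9, 0.1))
  scheme <- class_scheme(cutoffs = c(tag = 0.4, cd45 = 0.4))
  cls <- classify_cells(meas, scheme)
  expect_identical(cls, c("ctc", "immune", "ambiguous", "ambiguous"))
  expect_error(class_scheme(c(tag = 0.4),
                            rules = list(x = list(pos = "cd45", neg = "tag"))),
               "without cutoffs")
  expect_error(classify_cells(meas[, -5], scheme), "lack channel")
})

test_that("percent positive is exact and invariant to row order", {
  meas <- data.frame(label = 1:5, area = 30, centroid_row = 1, centroid_col = 1,
                     tag = c(0.9, 0.9, 0.9, 0.9, 0.1),
                     cd45 = 0.05,
                     marker = c(0.8, 0.8, 0.8, 0.1, 0.9))
  scheme <- class_scheme(cutoffs = c(tag = 0.4, cd45 = 0.4))
  cls <- classify_cells(meas, scheme)
  pp <- percent_positive(meas, cls, "ctc", "marker", 0.4)
  expect_equal(pp$percent, 75)
  perm <- sample(nrow(meas))
  pp2 <- percent_positive(meas[perm, ], cls[perm], "ctc", "marker", 0.4)
  expect_equal(pp2$percent, pp$percent)
  expect_equal(percent_positive(meas, cls, "ctc", "marker", 0.95)$percent, 0)
  expect_equal(percent_positive(meas, cls, "ctc", "marker", 0)$percent, 100)
  expect_error(percent_positive(meas, cls, "stromal", "marker", 0.4),
               "stromal")
})

test_that("segment-measure-classify reproduces the generator truth table", {
  sim <- simulate_if_image(n_ctc = 12, n_immune = 30,
                           frac_marker_positive = 0.5, noise_sd = 0, seed = 8)
  labels <- segment_nuclei(sim$stack, segmentation_config(min_area = 10))
  meas <- measure_cells(labels, sim$stack)
  expect_equal(nrow(meas), nrow(sim$truth))
  cls <- classify_cells(meas, class_scheme(c(tag = 0.4, cd45 = 0.4)))
  # match segmented objects to planted cells by centroid
  idx <- vapply(seq_len(nrow(meas)), function(i) {
    which.min((sim$truth$centroid_row - meas$centroid_row[i])^2 +
                (sim$truth$centroid_col - meas$centroid_col[i])^2)
  }, integer(1))
  expect_identical(sort(idx), seq_len(nrow(sim$truth)))
  expect_identical(cls, sim$truth$class[idx])
  expect_identical(meas$marker[order(idx)] >= 0.4, sim$truth$marker_positive)
})

test_that("otsu thresholding segments the synthetic image equally well", {
  sim <- simulate_if_image(n_ctc = 5, n_immune = 5, frac_marker_positive = 0,
                           seed = 2)
  labels <- segment_nuclei(sim$stack,
                           segmentation_config(nuclear_threshold = "otsu",
                                               min_area = 10))
  expect_equal(max(labels), 10)
})

test_that("image stacks round-trip through TIFF files and a manifest", {
  sim <- simulate_if_image(n_ctc = 2, n_immune = 2, frac_marker_positive = 1,
                           seed = 4)
  d <- withr::local_tempdir()
  manifest <- write_image_stack(sim$stack, d)
  back <- read_image_stack(manifest)
  expect_setequal(names(back$channels), names(sim$stack$channels))
  for (nm in names(back$channels)) {
    expect_equal(back$channels[[nm]], sim$stack$channels[[nm]],
                 tolerance = 1e-6)
  }
})

test_that("event gating recovers planted fractions and flags empty gates", {
  sim <- simulate_flow_events(n_gated = 50, n_outside = 100,
                              frac_marker_positive = 1, seed = 6)
  g <- gate_events(sim$events, gate_config(0.4, 0.4, 0.4))
  expect_equal(g$fraction, 1.0)
  expect_equal(g$n_gated, 50)

  none <- simulate_flow_events(n_gated = 0, n_outside = 20,
                               frac_marker_positive = 0, seed = 6)
  g0 <- gate_events(none$events, gate_config(0.4, 0.4, 0.4))
  expect_true(g0$undefined)
  expect_true(is.na(g0$fraction))
  expect_error(gate_events(data.frame(tag = 1, cd45 = 1), gate_config(0, 1, 0)),
               "marker")
})
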