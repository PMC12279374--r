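test_that("counting-frame rule: inclusion and exclusion edges", {
  fr <- counting_frame(0, 0, 9, 9)
  obj <- function(x, y, e = 0) data.frame(x = x, y = y, extent = e)
  expect_equal(nrow(counting_frame_filter(obj(4, 4), fr)), 1)     # inside
  expect_equal(nrow(counting_frame_filter(obj(0, 5), fr)), 1)     # left edge
  expect_equal(nrow(counting_frame_filter(obj(5, 0), fr)), 1)     # bottom
  expect_equal(nrow(counting_frame_filter(obj(9, 5), fr)), 0)     # right
  expect_equal(nrow(counting_frame_filter(obj(5, 9), fr)), 0)     # top
  # extent touching the exclusion line excludes the object
  expect_equal(nrow(counting_frame_filter(obj(8.5, 5, e = 0.5), fr)), 0)
  expect_equal(nrow(counting_frame_filter(obj(8.4, 5, e = 0.5), fr)), 1)
  # extension of the exclusion edge: right of the frame but touching y = 9
  expect_equal(nrow(counting_frame_filter(obj(5, 8.8, e = 0.3), fr)), 0)
})

test_that("counting-frame inclusion probability equals the area ratio", {
  set.seed(23)
  tile <- 4; fr <- counting_frame(0.5, 0.5, 2, 3)
  n <- 4000
  pts <- data.frame(x = runif(n, 0, tile), y = runif(n, 0, tile))
  frac <- nrow(counting_frame_filter(pts, fr)) / n
  p <- fr$area / tile^2
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(frac - p), 2 * se)
})

test_that("disector counting by id disappearance", {
  fr <- counting_frame(0, 0, 10, 10)
  mk <- function(ids) data.frame(id = ids, x = seq_along(ids),
                                 y = seq_along(ids))
  s <- dissector_sample(fr, 0.05, list(
    list(reference = mk(c("a", "b", "c")), lookup = mk(c("b", "c")))))
  expect_equal(dissector_count(s)$sum_qd, 1)
  s2 <- dissector_sample(fr, 0.05, list(
    list(reference = mk(c("a", "b")), lookup = mk(c("a", "b")))))
  expect_equal(dissector_count(s2)$sum_qd, 0)
  s3 <- dissector_sample(fr, 0.05, list(
    list(reference = mk("a"), lookup = mk(c("a", "zz")))))
  expect_error(dissector_count(s3, strict = TRUE), "integrity error")
})

test_that("density formula and degenerate inputs", {
  expect_equal(density_nv(12, 20, 81, 0.05), 12 / 81 * 1e9)
  expect_equal(density_nv(0, 20, 81, 0.05), 0)
  expect_error(density_nv(5, 0, 81, 0.05), "> 0")
  # additivity: splitting a disector set leaves Nv unchanged
  expect_equal(density_nv(7 + 5, 30, 81, 0.05),
               (7 + 5) / ((30) * 81 * 0.05) * 1e9)
})

test_that("disector counts equal the block's true top-ends in the frames", {
  blk <- generate_neuropil_block(density_per_mm3 = 4e8, n_pairs = 25,
                                 seed = 27)
  dc <- dissector_count(blk$sample)
  t_um <- blk$sample$thickness_t
  truth <- vapply(seq_len(nrow(blk$pair_info)), function(k) {
    i <- blk$pair_info$section[k]
    fx <- blk$pair_info$fx[k]; fy <- blk$pair_info$fy[k]
    tops <- blk$tops
    inz <- tops$z_top > i * t_um & tops$z_top <= (i + 1) * t_um
    inxy <- tops$x - fx >= 0 & tops$x - fx < 9 &
      tops$y - fy >= 0 & tops$y - fy < 9
    sum(inz & inxy)
  }, numeric(1))
  expect_equal(dc$qd, truth)
})

test_that("disector density is unbiased at the cortical density scale", {
  blk <- generate_neuropil_block(density_per_mm3 = 5.26e8, n_pairs = 400,
                                 seed = 29)
  dc <- dissector_count(blk$sample)
  nv <- density_nv(dc$sum_qd, 400, blk$sample$frame$area,
                   blk$sample$thickness_t)
  expect_lt(abs(nv / 5.26e8 - 1), 0.10)
})

test_that("Cavalieri estimator: arithmetic and degenerate input", {
  g <- point_grid(a_p = 0.64, hits_astro = 23, total_points = 100)
  r <- cavalieri_volume(g, thickness_t = 0.05)
  expect_equal(r$fraction_percent, 23)
  expect_equal(r$volume_um3, 0.64 * 23 * 0.05)
  all_hit <- cavalieri_volume(point_grid(0.64, 50, 50), 0.05)
  expect_equal(all_hit$fraction_percent, 100)
  expect_error(point_grid(0.64, 5, 4), "<=")
  expect_error(cavalieri_volume(point_grid(0.64, 0, numeric()), 0.05))
})

test_that("Cavalieri point counting is unbiased against voxel truth", {
  mask <- generate_astro_mask(fraction = 0.20, dim = c(200, 200),
                              pixel_um = 0.1, seed = 33)
  set.seed(34)
  # mean over 50 random grid offsets within 1 percentage point of truth
  ests <- replicate(50, {
    off <- runif(2, 0, 1)
    g <- sample_point_grid(mask, spacing_um = 1, offset_um = off)
    cavalieri_volume(g, 0.05)$fraction_percent
  })
  expect_lt(abs(mean(ests) - 100 * mask$fraction_true), 1)
  # three ~400-point grids land within 2 points
  three <- mean(ests[1:3])
  expect_lt(abs(three - 100 * mask$fraction_true), 2)
})

test_that("coverage classification and summary proportions", {
  expect_equal(classify_az_coverage(TRUE, TRUE, "spine")$klass, "both_sides")
  expect_equal(classify_az_coverage(TRUE, FALSE, "spine")$klass, "one_side")
  expect_equal(classify_az_coverage(FALSE, FALSE, "shaft")$klass, "none")
  expect_error(classify_az_coverage(NA, TRUE, "spine"), "missing")

  all_both <- data.frame(target = "spine", klass = rep("both_sides", 5))
  s <- coverage_summary(all_both)
  expect_equal(s$percent, c(100, 0, 0))
  one_each <- data.frame(target = "shaft",
                         klass = c("both_sides", "one_side", "none"))
  expect_equal(coverage_summary(one_each)$percent, rep(100 / 3, 3))

  # multinomial cohort matches its generating proportions (goodness of fit
  # across the three classes; summary must reproduce the sample exactly)
  set.seed(37)
  probs <- c(0.0869, 0.2373, 0.6758)
  n <- 600
  kl <- sample(c("both_sides", "one_side", "none"), n, replace = TRUE,
               prob = probs)
  s <- coverage_summary(data.frame(target = "spine", klass = kl))
  counts <- table(factor(kl, c("both_sides", "one_side", "none")))
  expect_equal(s$percent, as.numeric(100 * counts / n))
  expect_gt(stats::chisq.test(counts, p = probs)$p.value, 0.001)
  # classes are exhaustive and mutually exclusive
  expect_equal(sum(s$percent), 100)
})
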