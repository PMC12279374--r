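test_that("plane and cap distances match the analytic formulas exactly", {
  pl <- az_plane(c(0, 0, 0), c(0, 0, 1))
  expect_equal(min_membrane_distance(c(0, 0, 30), 25, pl), 17.5)
  expect_equal(min_membrane_distance(c(0, 0, 12.5), 25, pl), 0)
  expect_equal(min_membrane_distance(c(0, 0, 5), 25, pl), -7.5)
  # centre on the surface: maximal overlap is -diameter/2, within the
  # "never below -diameter" invariant
  expect_equal(min_membrane_distance(c(0, 0, 0), 25, pl), -12.5)
  expect_gte(min_membrane_distance(c(0, 0, 0), 25, pl), -25)

  set.seed(9)
  cap <- az_cap(center = c(100, -50, 200), R = 500, axis = c(1, 0, 0),
                theta = 0.5)
  # radial placement under the cap: p = R - rho - d/2 exactly
  for (rep in 1:20) {
    u <- runif_cone_test(cap$axis, cap$theta)
    rho <- runif(1, 50, 450); d <- runif(1, 20, 40)
    p <- min_membrane_distance(cap$center + rho * u, d, cap)
    expect_equal(p, 500 - rho - d / 2, tolerance = 1e-9)
  }
})

test_that("off-cap distances match a dense surface-sampling oracle", {
  set.seed(13)
  cap <- az_cap(center = c(0, 0, 0), R = 480, axis = c(0, 0, 1),
                theta = 0.6)
  # dense point sampling of the cap as the brute-force oracle
  n_s <- 2e5
  cosa <- runif(n_s, cos(cap$theta), 1)
  sina <- sqrt(1 - cosa^2); phi <- runif(n_s, 0, 2 * pi)
  surf <- 480 * cbind(sina * cos(phi), sina * sin(phi), cosa)
  # dense deterministic rim ring (grazing-incidence accuracy at the edge)
  rim_phi <- seq(0, 2 * pi, length.out = 8000)
  surf <- rbind(surf, 480 * cbind(sin(cap$theta) * cos(rim_phi),
                                  sin(cap$theta) * sin(rim_phi),
                                  cos(cap$theta)))
  centers <- matrix(rnorm(3 * 300), ncol = 3)
  centers <- centers / sqrt(rowSums(centers^2)) *
    runif(300, 100, 460)
  d <- runif(300, 20, 40)
  p <- min_membrane_distance(centers, d, cap)
  p_oracle <- min_dist_to_points(centers, surf) - d / 2
  expect_true(all(p <= p_oracle + 1e-9))
  expect_lt(max(abs(p - p_oracle)), 0.5)
})

test_that("mesh distances match the dense-sampling oracle within 0.5 nm", {
  set.seed(17)
  coh <- generate_bouton_cohort(load_profile("l1a"), seed = 17,
                                n_boutons = 1, with_vesicles = FALSE)
  labs <- vapply(coh$stacks, `[[`, "", "label")
  mesh <- preaz_mesh(coh$stacks[[which(labs == "preaz_line")[1]]])
  surf <- rbind(sample_mesh_points(mesh$triangles, 1e5),
                mesh_edge_points(mesh$triangles, h = 1))
  bb_lo <- apply(surf, 2, min) - 300
  bb_hi <- apply(surf, 2, max) + 300
  n <- 1000
  centers <- cbind(runif(n, bb_lo[1], bb_hi[1]),
                   runif(n, bb_lo[2], bb_hi[2]),
                   runif(n, bb_lo[3], bb_hi[3]))
  d <- runif(n, 20, 40)
  # keep configurations clear of the surface, where the sampling oracle is
  # itself accurate
  p <- min_membrane_distance(centers, d, mesh)
  keep <- p - (-d / 2) > 10
  p_oracle <- min_dist_to_points(centers[keep, , drop = FALSE],
                                 surf) - d[keep] / 2
  expect_true(all(p[keep] <= p_oracle + 1e-9))
  expect_lt(max(abs(p[keep] - p_oracle)), 0.5)
  expect_gt(sum(keep), 900)
})

test_that("pool classification: intervals, boundaries and partition", {
  pc <- classify_pools(c(5, 15, 100, 250, 400))
  expect_equal(pc$rrp_p10, 1)
  expect_equal(pc$rrp_p20, 2)
  expect_equal(pc$unassigned_20_60, 0)
  expect_equal(pc$rp_60_200, 1)
  expect_equal(pc$resting_gt200, 2)
  expect_equal(pc$resting_gt500, 0)

  empty <- classify_pools(numeric())
  expect_equal(empty$n_total, 0)
  expect_equal(empty$rrp_p20, 0)

  gap <- classify_pools(c(25, 40))
  expect_equal(gap$unassigned_20_60, 2)
  expect_equal(gap$rrp_p20 + gap$rp_60_200 + gap$resting_gt200, 0)

  # boundary values belong to the named pool
  bd <- classify_pools(c(10, 20, 60, 200, 500))
  expect_equal(bd$rrp_p10, 1)
  expect_equal(bd$rrp_p20, 2)
  expect_equal(bd$rp_60_200, 2)     # 60 and 200
  expect_equal(bd$resting_gt200, 1) # 500
  expect_equal(bd$resting_gt500, 1)
  expect_equal(bd$docked, 0)

  # partition invariant on random perimeter vectors
  set.seed(2)
  for (rep in 1:25) {
    p <- runif(200, -30, 1200)
    pc <- classify_pools(p)
    expect_equal(pc$rrp_p20 + pc$unassigned_20_60 + pc$rp_60_200 +
                   pc$resting_gt200, 200)
  }
})

test_that("docked counts and monotonicity under translation away from the AZ", {
  expect_equal(docked_count(c(-1, 0, 5)), 2)
  expect_equal(docked_count(numeric()), 0)
  set.seed(31)
  pl <- az_plane(c(0, 0, 0), c(0, 0, 1))
  centers <- cbind(runif(300, -400, 400), runif(300, -400, 400),
                   runif(300, 5, 600))
  d <- runif(300, 20, 40)
  prev <- NULL
  for (shift in c(0, 25, 60, 150)) {
    moved <- centers; moved[, 3] <- moved[, 3] + shift
    p <- min_membrane_distance(moved, d, pl)
    pc <- classify_pools(p)
    if (!is.null(prev)) {
      expect_lte(pc$rrp_p10, prev$rrp_p10)
      expect_lte(pc$rrp_p20, prev$rrp_p20)
      expect_lte(pc$docked, prev$docked)
    }
    prev <- pc
  }
})

test_that("vesicle volume statistics follow the sphere closed form", {
  v <- data.frame(diameter_nm = 25, vtype = "SV")
  r <- vesicle_stats(v, bouton_volume = 0.5)
  expect_equal(r$sv_volume_um3, pi * 25^3 / 6 * 1e-9, tolerance = 1e-12)
  none <- vesicle_stats(data.frame(diameter_nm = 58, vtype = "DCV"), 0.5)
  expect_equal(none$sv_volume_um3, 0)
  expect_equal(none$sv_percent_of_bouton, 0)
  expect_error(vesicle_stats(v, 0), "undefined")
  # cohort mean diameter recovers the configured truncated-normal mean
  set.seed(8)
  coh <- generate_bouton_cohort(load_profile("l1a"), seed = 8,
                                n_boutons = 5)
  sv <- coh$vesicles[coh$vesicles$vtype == "SV", ]
  expect_true(all(sv$diameter_nm >= 10 & sv$diameter_nm <= 60))
})

test_that("pipeline pool counts equal the generator's ground truth", {
  coh <- generate_bouton_cohort(load_profile("l1b"), seed = 19,
                                n_boutons = 6)
  mb <- coh$manifest$boutons
  pools <- pools_from_series(coh, az = coh$az)
  pools <- pools[match(mb$bouton_id, pools$bouton_id), ]
  expect_equal(pools$rrp_p10, mb$rrp_p10)
  expect_equal(pools$rrp_p20, mb$rrp_p20)
  expect_equal(pools$unassigned, mb$unassigned_20_60)
  expect_equal(pools$rp, mb$rp_60_200)
  expect_equal(pools$resting, mb$resting_gt200)
  expect_equal(pools$n_total, mb$n_total)
})
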