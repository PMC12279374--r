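test_that("polygon area matches closed forms and rejects bowties", {
  sq <- square_xy(1000)
  expect_equal(polygon_area(sq), 1e6)
  expect_equal(polygon_area(sq[4:1, ]), 1e6)  # orientation-independent
  tri <- cbind(c(0, 2000, 0), c(0, 0, 2000))
  expect_equal(polygon_area(tri), 2e6)
  bow <- cbind(c(0, 1000, 1000, 0), c(0, 1000, 0, 1000))
  expect_error(polygon_area(bow), "self-intersecting")
})

test_that("polygon area agrees with a pixel-counting oracle", {
  set.seed(11)
  for (rep in 1:3) {
    xy <- random_simple_polygon(20)
    a <- polygon_area(xy)
    a_pix <- pixel_area_oracle(xy, h = 2)
    expect_lt(abs(a / a_pix - 1), 0.005)
  }
})

test_that("stack volume: slab closed form, scaling law, gap interpolation", {
  meta <- default_meta()
  st <- contour_stack("b", "bouton",
                      list(contour(0, square_xy(1000), "bouton", "b")), meta)
  expect_equal(stack_volume(st), 0.05)  # 1 um^2 x 50 nm

  sc <- sqrt(2)
  st2 <- contour_stack("b", "bouton",
                       list(contour(0, square_xy(1000) * sc, "bouton", "b")),
                       meta)
  expect_equal(stack_volume(st2), 2 * stack_volume(st), tolerance = 1e-12)

  gap <- contour_stack("g", "bouton", list(
    contour(0, square_xy(1000), "bouton", "g"),
    contour(1, square_xy(1000), "bouton", "g"),
    contour(3, square_xy(2000), "bouton", "g")), meta)
  expect_warning(v <- stack_volume(gap), "interpolated")
  # areas 1, 1, (1+4)/2 interpolated, 4 um^2 over 50 nm each
  expect_equal(v, (1 + 1 + 2.5 + 4) * 0.05)
})

test_that("sphere stacks recover analytic volume and surface for r >= 5t", {
  set.seed(5)
  for (R in c(250, 492, 660)) {
    for (off in runif(2, 0, 50)) {
      st <- sphere_stack_fixture(R, offset = off)
      v <- stack_volume(st)
      s <- stack_surface_area(st)
      v_exact <- 4 / 3 * pi * R^3 * 1e-9
      s_exact <- 4 * pi * R^2 * 1e-6
      expect_lt(abs(v / v_exact - 1), 0.02,
                label = sprintf("volume rel err, R=%g", R))
      expect_lt(abs(s / s_exact - 1), 0.05,
                label = sprintf("surface rel err, R=%g", R))
    }
  }
  # the cohort calibration points: r = 0.492 um -> 0.50 um^3,
  # r = 0.66 um -> 5.47 um^2
  expect_equal(stack_volume(sphere_stack_fixture(492)), 0.50,
               tolerance = 0.02)
  expect_equal(stack_surface_area(sphere_stack_fixture(660)), 5.47,
               tolerance = 0.05)
})

test_that("surface area recovers an axis-aligned cuboid", {
  meta <- default_meta()
  cts <- lapply(0:9, function(i) contour(i, square_xy(1000), "bouton", "c"))
  st <- contour_stack("c", "bouton", cts, meta)
  # 2 caps of 1 um^2 + 4 walls of 1 x 0.5 um
  expect_equal(stack_surface_area(st), 4.0, tolerance = 0.03 * 4)
})

test_that("areas and volumes are scale-covariant on irregular stacks", {
  meta <- default_meta()
  set.seed(21)
  for (rep in 1:5) {
    phase <- runif(1, 0, 2 * pi)
    cts <- lapply(0:6, function(i) {
      phi <- seq(0, 2 * pi, length.out = 49)[-49]
      r <- 600 * (1 + 0.2 * sin(3 * phi + phase) + 0.05 * i)
      contour(i, cbind(r * cos(phi), r * sin(phi)), "bouton", "s")
    })
    st <- contour_stack("s", "bouton", cts, meta)
    s <- runif(1, 0.5, 2)
    meta2 <- series_meta("x", "p", "other",
                         section_thickness = 50 * s)
    cts2 <- lapply(st$contours, function(ct)
      contour(ct$section_index, ct$xy * s, "bouton", "s"))
    st2 <- contour_stack("s", "bouton", cts2, meta2)
    expect_equal(stack_volume(st2), stack_volume(st) * s^3,
                 tolerance = 1e-9)
    expect_equal(stack_surface_area(st2), stack_surface_area(st) * s^2,
                 tolerance = 1e-9)
  }
})

test_that("preaz ribbon: slab and trapezoid contracts hold", {
  # one section, 4 um line, t = 50 nm -> 0.20 um^2
  l1 <- list(list(section = 0, xy = cbind(c(0, 4000), c(0, 0))))
  r <- preaz_surface_area(l1, 50)
  expect_equal(r$sa_preaz, 0.20)
  expect_equal(r$l_preaz, 4.0)
  # two straight stacked lines, 3 and 5 um -> planar trapezoid 4 x 0.05
  l2 <- list(list(section = 0, xy = cbind(c(-1500, 1500), c(0, 0))),
             list(section = 1, xy = cbind(c(-2500, 2500), c(0, 0))))
  r2 <- preaz_surface_area(l2, 50)
  expect_equal(r2$sa_preaz, 0.20, tolerance = 1e-9)
  expect_equal(r2$l_preaz, 4.0)
  expect_error(preaz_surface_area(list(
    list(section = 0, xy = cbind(c(1, 1), c(2, 2)))), 50), "zero-length")
})

test_that("preaz ribbon recovers analytic spherical-cap areas", {
  t <- 50
  for (cs in list(c(1500, 50), c(800, 40))) {
    R <- cs[1]; th <- cs[2] * pi / 180
    zs <- seq(-R, R, by = t); zs <- zs[abs(zs) < R * sin(th)]
    lines <- lapply(seq_along(zs), function(k) {
      rho <- sqrt(R^2 - zs[k]^2)
      psi <- acos(min(1, R * cos(th) / rho))
      phi <- seq(-psi, psi, length.out = 33)
      list(section = k, xy = cbind(rho * cos(phi), rho * sin(phi)))
    })
    est <- preaz_surface_area(lines, t)$sa_preaz
    truth <- 2 * pi * R^2 * (1 - cos(th)) * 1e-6
    expect_lt(abs(est / truth - 1), 0.05)
  }
})

test_that("psd perimeter-ratio formula is exact and homogeneous", {
  expect_equal(psd_area_from_ratio(0.20, 1, 1), 0.20)
  expect_equal(psd_area_from_ratio(0.20, 0, 1), 0)
  # the published sublaminar pairing: PreAZ 0.18 with ratio 7/6 -> PSD 0.21
  expect_equal(round(psd_area_from_ratio(0.18, 7, 6), 2), 0.21)
  expect_error(psd_area_from_ratio(0.2, 1, 0), "undefined")
  set.seed(3)
  for (rep in 1:10) {
    sa <- runif(1); lp <- runif(1, 0.1, 2); lq <- runif(1, 0.1, 2)
    k <- runif(1, 0.1, 10)
    expect_equal(psd_area_from_ratio(k * sa, lq, lp),
                 k * psd_area_from_ratio(sa, lq, lp), tolerance = 1e-12)
  }
})

test_that("cleft width averages the lateral edges", {
  cm <- cleft_width(20, 24, 30)
  expect_equal(cm$lateral_mean, 22)
  expect_equal(cm$central, 30)
  expect_equal(cleft_width(17, 17, 30)$lateral_mean, 17)
  expect_error(cleft_width(-1, 5, 5), ">= 0")
})

test_that("mitochondrial volume fraction", {
  expect_equal(mito_volume_fraction(0.50, 0.035), 7.0)
  expect_equal(mito_volume_fraction(0.50, numeric()), 0)
  expect_equal(mito_volume_fraction(0.5, c(0.02, 0.015)), 7.0)
  expect_error(mito_volume_fraction(0, 0.01), "undefined")
})
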