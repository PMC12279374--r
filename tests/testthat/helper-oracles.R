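# Independent oracles and fixture builders used across the suite. These stay
# deliberately naive: brute force, enumeration and closed forms only.

default_meta <- function(t = 50, n_sections = 100L)
  series_meta("test", "p0", "other", section_thickness = t,
              n_sections = n_sections)

square_xy <- function(side = 1000, cx = 0, cy = 0)
  cbind(cx + c(0, side, side, 0), cy + c(0, 0, side, side))

# Sphere sliced into circular contours at section mid-planes.
sphere_stack_fixture <- function(R, t = 50, offset = 0, n_vertices = 64L,
                                 label = "bouton", id = "s1") {
  zc <- R + t + offset
  i <- seq(0, ceiling((zc + R) / t))
  z <- i * t
  keep <- abs(z - zc) < R
  cts <- lapply(which(keep), function(k) {
    r <- sqrt(R^2 - (z[k] - zc)^2)
    phi <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
    contour(i[k], cbind(r * cos(phi), r * sin(phi)), label, id)
  })
  contour_stack(id, label, cts, default_meta(t))
}

# smooth star-shaped (hence simple) random polygon
random_simple_polygon <- function(n = 20, rmin = 500, rmax = 1500) {
  phi <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, rmin, rmax)
  cbind(r * cos(phi), r * sin(phi))
}

# Even-odd point-in-polygon for matrices of query points.
points_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]; xj <- xy[j, 1]; yj <- xy[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Pixel-counting polygon area at grid pitch h (nm^2).
pixel_area_oracle <- function(xy, h = 2) {
  xs <- seq(min(xy[, 1]) + h / 2, max(xy[, 1]), by = h)
  ys <- seq(min(xy[, 2]) + h / 2, max(xy[, 2]), by = h)
  total <- 0
  for (yy in ys) {
    inside <- points_in_polygon(xs, rep(yy, length(xs)), xy)
    total <- total + sum(inside)
  }
  total * h^2
}

# Two-sided exact Mann-Whitney p by full enumeration of group assignments,
# doubling the smaller tail (the convention used for exact U tests).
perm_mwu_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  u_of <- function(sel) {
    x <- pooled[sel]; y <- pooled[-sel]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  us <- apply(idx, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

naive_describe <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  v <- sum((x - m)^2) / (n - 1)
  s <- sqrt(v)
  xs <- sort(x)
  q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  }
  g1 <- (sum((x - m)^3) / n) / (sum((x - m)^2) / n)^1.5
  list(n = n, mean = m, sd = s, variance = v, median = q(0.5),
       iqr = q(0.75) - q(0.25), cv = s / m,
       skewness = g1 * sqrt(n * (n - 1)) / (n - 2))
}

# Uniform points on a triangle mesh, area-weighted: the brute-force surface
# oracle for distance computations.
sample_mesh_points <- function(tri, n) {
  A <- tri[, 1:3, drop = FALSE]
  B <- tri[, 4:6, drop = FALSE]
  C <- tri[, 7:9, drop = FALSE]
  ab <- B - A; ac <- C - A
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  w <- sqrt(rowSums(cr^2)) / 2
  k <- sample.int(nrow(tri), n, replace = TRUE, prob = w)
  u <- runif(n); v <- runif(n)
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
  A[k, ] + u * ab[k, ] + v * ac[k, ]
}

# Deterministic subdivision of every triangle edge at pitch h (includes all
# vertices). Random area samples alone converge only first-order near
# boundary vertices under grazing incidence; adding edge points restores
# second-order accuracy of the brute-force oracle everywhere.
mesh_edge_points <- function(tri, h = 1) {
  pts <- list()
  for (e in list(c(1, 4), c(4, 7), c(7, 1))) {
    P <- tri[, e[1]:(e[1] + 2), drop = FALSE]
    Q <- tri[, e[2]:(e[2] + 2), drop = FALSE]
    len <- sqrt(rowSums((Q - P)^2))
    for (i in seq_len(nrow(tri))) {
      k <- max(2, ceiling(len[i] / h) + 1)
      tt <- seq(0, 1, length.out = k)
      pts[[length(pts) + 1L]] <-
        cbind(P[i, 1] + tt * (Q[i, 1] - P[i, 1]),
              P[i, 2] + tt * (Q[i, 2] - P[i, 2]),
              P[i, 3] + tt * (Q[i, 3] - P[i, 3]))
    }
  }
  do.call(rbind, pts)
}

min_dist_to_points <- function(centers, surf_pts) {
  vapply(seq_len(nrow(centers)), function(i) {
    d2 <- (surf_pts[, 1] - centers[i, 1])^2 +
      (surf_pts[, 2] - centers[i, 2])^2 +
      (surf_pts[, 3] - centers[i, 3])^2
    sqrt(min(d2))
  }, numeric(1))
}

# rejection-sampled uniform direction inside a cone (tiny-n test helper)
runif_cone_test <- function(axis, theta) {
  repeat {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    if (sum(v * axis) >= cos(theta)) return(v)
  }
}

zero_variance_profile <- function(p10 = 4, rp = 470, rest = 2900) {
  cohort_profile(list(
    name = "custom", n_boutons = 1,
    bouton_volume = list(mean = 0.50, sd = 0),
    mito_fraction = list(mean = 7.21, sd = 0),
    preaz_area = list(mean = 0.20, sd = 0),
    psd_ratio = list(mean = 1.10, sd = 0),
    sv_diameter = list(mean = 25.03, sd = 0),
    pool_targets = list(
      rrp_p10 = list(mean = p10, sd = 0),
      rrp_p20_extra = list(mean = 0, sd = 0),
      unassigned_20_60 = list(mean = 0, sd = 0),
      rp_60_200 = list(mean = rp, sd = 0),
      resting_gt200 = list(mean = rest, sd = 0)),
    docked = list(mean = 3.56, sd = 0),
    cleft = list(lateral = list(mean = 21.75, sd = 0),
                 central = list(mean = 29.63, sd = 0)),
    coverage_probs = list(spine = c(0.0869, 0.2373, 0.6757),
                          shaft = c(0.0854, 0.1644, 0.7502)),
    density_per_mm3 = 5.26e8,
    spine_fraction = 0.8))
}
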