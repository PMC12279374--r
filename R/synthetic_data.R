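# Synthetic serial-section cohorts with exact ground truth.
#
# Boutons are modelled as spheres whose size, mitochondrial content, active
# zone geometry and vesicle pool composition are drawn from distributions
# calibrated to published layer-1 cohort means and SDs. Spheres are chosen
# deliberately: they give closed-form truth for volume, surface area,
# cap-patch area and vesicle-to-cap distance, so every pipeline measurement
# can be checked against an analytic oracle. All positive quantities are
# drawn from truncated normals whose location is solved so the
# post-truncation (and, for counts, post-rounding) mean equals the
# calibration mean; per-object draws use stratified inverse-CDF sampling,
# which preserves the marginal distribution while tightening cohort means.

#' Load a shipped cohort profile
#'
#' Profiles `"l1"`, `"l1a"` and `"l1b"` encode the layer-1 calibration
#' (bouton size, mitochondrial fraction, active-zone geometry, vesicle pool
#' targets, docked counts, cleft widths, coverage proportions and synapse
#' density). A file path to a custom YAML profile is also accepted.
#'
#' @param name profile name or path to a YAML file
#' @return object of class `cohort_profile`
#' @export
load_profile <- function(name = c("l1", "l1a", "l1b")) {
  path <- if (file.exists(name[1])) {
    name[1]
  } else {
    name <- match.arg(name)
    system.file("extdata", "profiles", paste0(name, ".yaml"),
                package = "synstereo", mustWork = TRUE)
  }
  cohort_profile(yaml::read_yaml(path))
}

#' Validate and construct a cohort profile
#'
#' @param x named list of profile fields (see the shipped YAML files for the
#'   schema)
#' @return object of class `cohort_profile`
#' @export
cohort_profile <- function(x) {
  need <- c("name", "n_boutons", "bouton_volume", "mito_fraction",
            "preaz_area", "psd_ratio", "sv_diameter", "pool_targets",
            "docked", "cleft", "coverage_probs", "density_per_mm3",
            "spine_fraction")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("profile missing fields: ",
                         paste(miss, collapse = ", "))
  ms_fields <- c("bouton_volume", "mito_fraction", "preaz_area", "psd_ratio",
                 "sv_diameter", "docked")
  for (f in c(ms_fields)) {
    if (x[[f]]$sd < 0) stop("profile: negative sd in ", f)
  }
  for (p in names(x$pool_targets))
    if (x$pool_targets[[p]]$sd < 0) stop("profile: negative sd in pool ", p)
  for (tgt in names(x$coverage_probs)) {
    pr <- unlist(x$coverage_probs[[tgt]])
    if (any(pr < 0)) stop("profile: negative coverage probability")
    x$coverage_probs[[tgt]] <- pr / sum(pr)
  }
  if (x$spine_fraction < 0 || x$spine_fraction > 1)
    stop("profile: spine_fraction must be in [0,1]")
  structure(x, class = "cohort_profile")
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat(sprintf("<cohort_profile> %s: %d boutons, V=%.2f+-%.2f um^3, mito %.2f%%, p10 %.2f\n",
              x$name, x$n_boutons, x$bouton_volume$mean, x$bouton_volume$sd,
              x$mito_fraction$mean, x$pool_targets$rrp_p10$mean))
  invisible(x)
}

# circle contour as an implicitly closed polygon
circle_polygon <- function(cx, cy, r, n = 64L) {
  phi <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(phi), cy + r * sin(phi))
}

# Slice a sphere into per-section circle contours. Sections are the z-levels
# i * t (mid-planes) with |z - zc| < R.
sphere_sections <- function(R, zc, t) {
  i <- seq(floor((zc - R) / t), ceiling((zc + R) / t))
  z <- i * t
  keep <- abs(z - zc) < R
  data.frame(section = i[keep], z = z[keep],
             r = sqrt(pmax(0, R^2 - (z[keep] - zc)^2)))
}

sphere_stack <- function(object_id, label, cx, cy, zc, R, meta, n_vertices = 64L) {
  s <- sphere_sections(R, zc, meta$section_thickness)
  # a tiny object living between two mid-planes still needs one contour
  if (nrow(s) == 0) {
    i0 <- round(zc / meta$section_thickness)
    s <- data.frame(section = i0, z = i0 * meta$section_thickness, r = R / 2)
  }
  cts <- lapply(seq_len(nrow(s)), function(k)
    contour(s$section[k], circle_polygon(cx, cy, s$r[k], n_vertices),
            label, object_id))
  contour_stack(object_id, label, cts, meta)
}

# Arc polylines of a spherical cap with horizontal axis, per section.
# Returns list of list(section, xy) entries (possibly empty).
cap_arc_lines <- function(cx, cy, zc, R, phi0, theta, t, radius_scale = 1,
                          angle_scale = 1, n_pts = 17L) {
  s <- sphere_sections(R, zc, t)
  out <- list()
  for (k in seq_len(nrow(s))) {
    rho <- s$r[k]
    if (rho <= 0) next
    co <- R * cos(theta) / rho
    if (co >= 1) next
    psi <- acos(max(-1, co)) * angle_scale
    if (psi <= 0) next
    phi <- seq(phi0 - psi, phi0 + psi, length.out = n_pts)
    rr <- rho * radius_scale
    out[[length(out) + 1L]] <- list(
      section = s$section[k],
      xy = cbind(cx + rr * cos(phi), cy + rr * sin(phi)))
  }
  out
}

#' Generate a calibrated synthetic bouton cohort
#'
#' Each bouton is a sphere sliced at the section thickness into contour
#' stacks, with interior mitochondria hitting a drawn volume fraction, a
#' spherical-cap PreAZ patch of drawn area (horizontal axis, so the section
#' planes cut it into open arc polylines), matching PSD polylines scaled by
#' the drawn perimeter ratio, and a vesicle cloud whose membrane distances
#' to the cap are placed pool-first: distances are sampled inside the target
#' pool interval and positions constructed (or rejection-sampled for the
#' resting pool) to realise them exactly, so pool membership is true by
#' construction and recorded in the manifest.
#'
#' @param profile a [cohort_profile()]
#' @param seed integer seed (the generator is fully deterministic under it)
#' @param n_boutons number of boutons (default from the profile)
#' @param with_vesicles generate the vesicle cloud (TRUE) or only the
#'   geometry (FALSE; much faster when only volumes are needed)
#' @param n_vertices polygon vertices per contour
#' @return list with `meta`, `stacks`, `vesicles` (flat data.frame),
#'   `az` (named list of analytic `az_surface` patches per bouton) and
#'   `manifest` (list of data.frames `boutons`, `vesicles` holding the
#'   ground truth)
#' @export
generate_bouton_cohort <- function(profile, seed = NULL,
                                   n_boutons = profile$n_boutons,
                                   with_vesicles = TRUE, n_vertices = 64L) {
  stopifnot(inherits(profile, "cohort_profile"))
  if (!is.null(seed)) set.seed(seed)
  t <- 50
  n <- n_boutons
  V <- rpos_calibrated(n, profile$bouton_volume$mean,
                       profile$bouton_volume$sd, lower = 0.10)
  f_mito <- rpos_calibrated(n, profile$mito_fraction$mean,
                            profile$mito_fraction$sd, lower = 0.5,
                            upper = 40)
  a_preaz <- rpos_calibrated(n, profile$preaz_area$mean,
                             profile$preaz_area$sd, lower = 0.02,
                             upper = 0.6)
  ratio <- rpos_calibrated(n, profile$psd_ratio$mean, profile$psd_ratio$sd,
                           lower = 0.5, upper = 2)
  pt <- profile$pool_targets
  counts <- list(
    p10 = rcount_calibrated(n, pt$rrp_p10$mean, pt$rrp_p10$sd),
    p20x = rcount_calibrated(n, pt$rrp_p20_extra$mean, pt$rrp_p20_extra$sd),
    un = rcount_calibrated(n, pt$unassigned_20_60$mean,
                           pt$unassigned_20_60$sd),
    rp = rcount_calibrated(n, pt$rp_60_200$mean, pt$rp_60_200$sd),
    rest = rcount_calibrated(n, pt$resting_gt200$mean, pt$resting_gt200$sd))
  cl <- profile$cleft
  cleft_l1 <- rtruncnorm(n, cl$lateral$mean, cl$lateral$sd, lower = 5)
  cleft_l2 <- rtruncnorm(n, cl$lateral$mean, cl$lateral$sd, lower = 5)
  cleft_c <- rtruncnorm(n, cl$central$mean, cl$central$sd, lower = 5)
  target <- ifelse(stats::runif(n) < profile$spine_fraction, "spine", "shaft")
  klasses <- c("both_sides", "one_side", "none")
  coverage <- vapply(target, function(tg)
    sample(klasses, 1, prob = profile$coverage_probs[[tg]]), "")
  R_nm <- (3 * V / (4 * pi))^(1 / 3) * 1e3
  zc <- R_nm + t * (1 + stats::runif(n))           # keep all sections >= 0
  cx <- stats::runif(n, 0, 20000); cy <- stats::runif(n, 0, 20000)
  phi0 <- stats::runif(n, 0, 2 * pi)
  meta <- series_meta(paste0("sim-", profile$name), "sim",
                      if (profile$name %in% c("L1a", "L1b")) profile$name
                      else "other",
                      section_thickness = t,
                      n_sections = as.integer(ceiling(max(zc + R_nm) / t) + 1))

  stacks <- list(); az <- list()
  ves_rows <- list(); man_ves <- list()
  man_b <- vector("list", n)
  sv_mean <- profile$sv_diameter$mean; sv_sd <- profile$sv_diameter$sd
  for (i in seq_len(n)) {
    bid <- sprintf("b%03d", i)
    R <- R_nm[i]
    stacks[[length(stacks) + 1L]] <-
      sphere_stack(bid, "bouton", cx[i], cy[i], zc[i], R, meta, n_vertices)
    # mitochondria: 1-3 interior spheres realising the drawn fraction
    Vb <- 4 / 3 * pi * R^3
    v_mito_total <- f_mito[i] / 100 * Vb
    k <- sample(1:3, 1, prob = c(0.5, 0.3, 0.2))
    w <- stats::runif(k, 0.5, 1); w <- w / sum(w)
    r_m <- (3 * v_mito_total * w / (4 * pi))^(1 / 3)
    for (j in seq_len(k)) {
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      rho <- stats::runif(1, 0, max(0, R - r_m[j] - 20))
      ctr <- c(cx[i], cy[i], zc[i]) + rho * dir
      stacks[[length(stacks) + 1L]] <-
        sphere_stack(sprintf("%s-m%d", bid, j), "mitochondrion",
                     ctr[1], ctr[2], ctr[3], r_m[j], meta,
                     n_vertices = 32L)
    }
    # PreAZ spherical cap, horizontal axis
    a_nm2 <- a_preaz[i] * 1e6
    cos_theta <- max(1 - a_nm2 / (2 * pi * R^2), 0.2)
    theta <- acos(cos_theta)
    axis <- c(cos(phi0[i]), sin(phi0[i]), 0)
    cap <- az_cap(c(cx[i], cy[i], zc[i]), R, axis, theta)
    az[[bid]] <- cap
    a_true <- 2 * pi * R^2 * (1 - cos_theta) * 1e-6
    pre_lines <- cap_arc_lines(cx[i], cy[i], zc[i], R, phi0[i], theta, t)
    if (length(pre_lines)) {
      cts <- lapply(pre_lines, function(p)
        contour(p$section, p$xy, "preaz_line", paste0(bid, "-preaz")))
      stacks[[length(stacks) + 1L]] <-
        contour_stack(paste0(bid, "-preaz"), "preaz_line", cts, meta)
      r_scale <- (R + cleft_c[i]) / R
      psd_lines <- cap_arc_lines(cx[i], cy[i], zc[i], R, phi0[i], theta, t,
                                 radius_scale = r_scale,
                                 angle_scale = ratio[i] / r_scale)
      cts2 <- lapply(psd_lines, function(p)
        contour(p$section, p$xy, "psd_line", paste0(bid, "-psd")))
      stacks[[length(stacks) + 1L]] <-
        contour_stack(paste0(bid, "-psd"), "psd_line", cts2, meta)
    }
    pools <- c(p10 = counts$p10[i], p20x = counts$p20x[i], un = counts$un[i],
               rp = counts$rp[i], rest = counts$rest[i])
    if (with_vesicles) {
      vv <- place_vesicles(pools, cap, R, sv_mean, sv_sd, bid)
      ndcv <- stats::rpois(1, 10)
      if (ndcv > 0) {
        dd <- rtruncnorm(ndcv, 57.97, 6.45, lower = 40, upper = 80)
        dirm <- matrix(stats::rnorm(3 * ndcv), ncol = 3)
        dirm <- dirm / sqrt(rowSums(dirm^2))
        rr <- (R - dd / 2 - 1) * stats::runif(ndcv)^(1 / 3)
        ctr <- sweep(dirm * rr, 2, c(cx[i], cy[i], zc[i]), `+`)
        vv <- rbind(vv, data.frame(
          x = ctr[, 1] - cx[i], y = ctr[, 2] - cy[i], z = ctr[, 3] - zc[i],
          diameter = dd, pool = "dcv", p_true = NA_real_,
          bouton_id = bid, stringsAsFactors = FALSE))
      }
      vv$x <- vv$x + cx[i]; vv$y <- vv$y + cy[i]; vv$z <- vv$z + zc[i]
      vv$vesicle_id <- sprintf("%s-v%05d", bid, seq_len(nrow(vv)))
      ves_rows[[i]] <- vv
    }
    man_b[[i]] <- data.frame(
      bouton_id = bid, sublamina = meta$sublamina, target = target[i],
      radius_nm = R, volume_um3 = Vb * 1e-9,
      surface_um2 = 4 * pi * R^2 * 1e-6,
      mito_volume_um3 = v_mito_total * 1e-9, n_mito = k,
      mito_fraction = f_mito[i],
      preaz_area_um2 = a_true, psd_ratio = ratio[i],
      cleft_lateral_left = cleft_l1[i], cleft_lateral_right = cleft_l2[i],
      cleft_central = cleft_c[i], coverage = coverage[i],
      rrp_p10 = pools[["p10"]],
      rrp_p20 = pools[["p10"]] + pools[["p20x"]],
      unassigned_20_60 = pools[["un"]], rp_60_200 = pools[["rp"]],
      resting_gt200 = pools[["rest"]],
      n_total = sum(pools), stringsAsFactors = FALSE)
  }
  manifest_b <- do.call(rbind, man_b)
  vesicles <- if (with_vesicles && length(ves_rows)) {
    vv <- do.call(rbind, ves_rows)
    data.frame(vesicle_id = vv$vesicle_id, bouton_id = vv$bouton_id,
               x_nm = vv$x, y_nm = vv$y, z_nm = vv$z,
               diameter_nm = vv$diameter,
               vtype = ifelse(vv$pool == "dcv", "DCV", "SV"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(vesicle_id = character(), bouton_id = character(),
               x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
               diameter_nm = numeric(), vtype = character(),
               stringsAsFactors = FALSE)
  }
  manifest_v <- if (with_vesicles && length(ves_rows)) {
    vv <- do.call(rbind, ves_rows)
    data.frame(vesicle_id = vv$vesicle_id, bouton_id = vv$bouton_id,
               pool = vv$pool, p_true = vv$p_true,
               stringsAsFactors = FALSE)
  } else NULL
  list(meta = meta, stacks = stacks, vesicles = vesicles, az = az,
       manifest = list(boutons = manifest_b, vesicles = manifest_v))
}

# Distance-first vesicle placement against a spherical-cap PreAZ.
# Returns data.frame with centre coordinates relative to the sphere centre.
place_vesicles <- function(pools, cap, R, sv_mean, sv_sd, bid) {
  n_direct <- pools[["p10"]] + pools[["p20x"]] + pools[["un"]] +
    pools[["rp"]]
  p <- c(stats::runif(pools[["p10"]], 0, 10),
         stats::runif(pools[["p20x"]], 10, 20),
         stats::runif(pools[["un"]], 20, 60),
         stats::runif(pools[["rp"]], 60, 200))
  pool_lab <- rep(c("rrp_p10", "rrp_p20", "unassigned", "rp"),
                  times = c(pools[["p10"]], pools[["p20x"]], pools[["un"]],
                            pools[["rp"]]))
  d <- rtruncnorm(n_direct, sv_mean, sv_sd, lower = 10, upper = 60)
  s <- pmin(p + d / 2, R - 5)        # centre must stay inside the sphere
  p <- s - d / 2                     # distances re-derived after clamping
  dirs <- runif_cone(n_direct, cap$axis, cap$theta)
  ctr <- dirs * (R - s)
  out <- data.frame(x = ctr[, 1], y = ctr[, 2], z = ctr[, 3], diameter = d,
                    pool = pool_lab, p_true = p, bouton_id = bid,
                    stringsAsFactors = FALSE)
  # resting pool: rejection sampling of uniform interior positions whose
  # exact analytic distance to the cap exceeds 200 nm
  need <- pools[["rest"]]
  acc <- list()
  guard <- 0L
  while (need > 0 && guard < 200L) {
    guard <- guard + 1L
    m <- max(200L, ceiling(need * 1.6))
    dd <- rtruncnorm(m, sv_mean, sv_sd, lower = 10, upper = 60)
    dirm <- matrix(stats::rnorm(3 * m), ncol = 3)
    dirm <- dirm / sqrt(rowSums(dirm^2))
    rr <- (R - dd / 2 - 1) * stats::runif(m)^(1 / 3)
    pts <- dirm * rr
    pv <- min_membrane_distance(sweep(pts, 2, cap$center, `+`), dd, cap)
    ok <- which(pv > 200)
    if (length(ok)) {
      take <- utils::head(ok, need)
      acc[[length(acc) + 1L]] <- data.frame(
        x = pts[take, 1], y = pts[take, 2], z = pts[take, 3],
        diameter = dd[take], pool = "resting", p_true = pv[take],
        bouton_id = bid, stringsAsFactors = FALSE)
      need <- need - length(take)
    }
  }
  if (need > 0)
    stop(sprintf("generation error: bouton %s too small for its resting pool",
                 bid))
  rbind(out, do.call(rbind, acc))
}

#' Generate a synthetic neuropil block for disector counting
#'
#' Synapses are short vertical segments whose top ends are a homogeneous
#' Poisson process in the block; each section records the objects whose
#' segment intersects its 50-nm slab, with persistent ids. A set of
#' reference/look-up pairs with a shared unbiased counting frame is drawn
#' from the block.
#'
#' @param density_per_mm3 true synapse density (>= 0)
#' @param block_um block dimensions c(x, y, z) in um
#' @param n_pairs number of disector pairs to sample
#' @param frame_um counting-frame side length, um (frame is square, placed
#'   with a margin inside the block)
#' @param thickness_um section thickness, um
#' @param seed integer seed
#' @return list with `sample` (a [dissector_sample()]), `truth_density` and
#'   `n_objects`
#' @export
generate_neuropil_block <- function(density_per_mm3 = 5.26e8,
                                    block_um = c(20, 20, 6), n_pairs = 20,
                                    frame_um = 9, thickness_um = 0.05,
                                    seed = NULL) {
  stopifnot(density_per_mm3 >= 0)
  if (!is.null(seed)) set.seed(seed)
  dens_um3 <- density_per_mm3 / 1e9
  vol <- prod(block_um)
  n <- stats::rpois(1, dens_um3 * vol)
  zt <- stats::runif(n, 0, block_um[3])
  xs <- stats::runif(n, 0, block_um[1]); ys <- stats::runif(n, 0, block_um[2])
  len <- stats::runif(n, 0.15, 0.4)
  nsec <- floor(block_um[3] / thickness_um)
  margin <- 0.5
  frame <- counting_frame(0, 0, frame_um, frame_um)
  pairs <- vector("list", n_pairs)
  sec_objects <- function(i, fx, fy) {
    lo <- i * thickness_um; hi <- (i + 1) * thickness_um
    keep <- which(zt > lo & (zt - len) < hi)
    data.frame(id = keep, x = xs[keep] - fx, y = ys[keep] - fy)
  }
  pair_info <- data.frame(section = integer(n_pairs), fx = numeric(n_pairs),
                          fy = numeric(n_pairs))
  for (k in seq_len(n_pairs)) {
    i <- sample.int(nsec - 1L, 1) - 1L
    fx <- stats::runif(1, margin, block_um[1] - frame_um - margin)
    fy <- stats::runif(1, margin, block_um[2] - frame_um - margin)
    pairs[[k]] <- list(reference = sec_objects(i, fx, fy),
                       lookup = sec_objects(i + 1L, fx, fy))
    pair_info[k, ] <- list(i, fx, fy)
  }
  list(sample = dissector_sample(frame, thickness_um, pairs),
       truth_density = density_per_mm3, n_objects = n,
       tops = data.frame(id = seq_len(n), x = xs, y = ys, z_top = zt),
       pair_info = pair_info)
}

#' Generate tomography-style active-zone configurations
#'
#' Per active zone, a docked-vesicle count drawn from a discretised,
#' moment-matched truncated normal; docked vesicles are placed in membrane
#' contact with the planar PreAZ patch (perimeter p <= 0) and a Poisson
#' number of non-docked vesicles at p > 0.
#'
#' @param docked_mean,docked_sd calibration of the docked count per AZ
#' @param n_az number of active zones
#' @param sv_diameter c(mean, sd) of the tomography-mode vesicle diameter, nm
#' @param n_free_mean mean number of non-docked vesicles per AZ
#' @param seed integer seed
#' @return list with `azs` (list of `list(az, centers, diameters)`),
#'   `truth_docked` (integer vector)
#' @export
generate_tomo_az <- function(docked_mean = 3.56, docked_sd = 1.36,
                             n_az = 100, sv_diameter = c(30.29, 4.67),
                             n_free_mean = 20, seed = NULL) {
  stopifnot(docked_mean >= 0)
  if (!is.null(seed)) set.seed(seed)
  k <- rcount_calibrated(n_az, docked_mean, docked_sd)
  azs <- vector("list", n_az)
  for (i in seq_len(n_az)) {
    az <- az_plane(c(0, 0, 0), c(0, 0, 1), radius = 250)
    nf <- stats::rpois(1, n_free_mean)
    nd <- k[i]
    d <- rtruncnorm(nd + nf, sv_diameter[1], sv_diameter[2],
                    lower = 15, upper = 50)
    p <- c(if (nd > 0) stats::runif(nd, -0.3 * d[seq_len(nd)], 0),
           if (nf > 0) stats::runif(nf, 1, 300))
    h <- p + d / 2
    phi <- stats::runif(nd + nf, 0, 2 * pi)
    r <- 200 * sqrt(stats::runif(nd + nf))
    azs[[i]] <- list(az = az,
                     centers = cbind(r * cos(phi), r * sin(phi), h),
                     diameters = d)
  }
  list(azs = azs, truth_docked = as.integer(k))
}

#' Synthetic astrocytic neuropil mask
#'
#' A smooth Gaussian random field thresholded at the empirical quantile so
#' that exactly the requested fraction of pixels is astrocytic; the voxel
#' fraction is the ground truth for Cavalieri point-count estimates.
#'
#' @param fraction target astrocytic area fraction (0..1)
#' @param dim pixel dimensions c(nx, ny)
#' @param pixel_um pixel size, um
#' @param smooth half-width of the smoothing kernel, pixels
#' @param seed integer seed
#' @return list with `mask` (logical matrix), `pixel_um`,
#'   `fraction_true` (realised pixel fraction)
#' @export
generate_astro_mask <- function(fraction = 0.2323, dim = c(200, 200),
                                pixel_um = 0.1, smooth = 8, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  f <- matrix(stats::rnorm(prod(dim)), dim[1], dim[2])
  kern <- stats::dnorm(seq(-smooth, smooth), sd = smooth / 2)
  kern <- kern / sum(kern)
  smooth1 <- function(m) {
    m <- apply(m, 2, function(col)
      stats::filter(c(col, col, col), kern, circular = TRUE)[
        (length(col) + 1):(2 * length(col))])
    m
  }
  f <- smooth1(f); f <- t(smooth1(t(f)))
  npix <- prod(dim)
  kcount <- round(fraction * npix)
  mask <- matrix(rank(f, ties.method = "first") > npix - kcount,
                 dim[1], dim[2])
  list(mask = mask, pixel_um = pixel_um, fraction_true = kcount / npix)
}

#' Overlay a point grid on a mask
#'
#' Samples the mask at regular grid points with a given offset and returns
#' the hit counts as a [point_grid()], for Cavalieri estimation.
#'
#' @param mask_obj result of [generate_astro_mask()]
#' @param spacing_um grid spacing, um
#' @param offset_um length-2 offset of the first grid point, um
#' @return a [point_grid()] with `a_p = spacing_um^2`
#' @export
sample_point_grid <- function(mask_obj, spacing_um = 0.8,
                              offset_um = c(0, 0)) {
  px <- mask_obj$pixel_um
  nx <- nrow(mask_obj$mask); ny <- ncol(mask_obj$mask)
  gx <- seq(offset_um[1], nx * px - 1e-9, by = spacing_um)
  gy <- seq(offset_um[2], ny * px - 1e-9, by = spacing_um)
  ix <- pmin(pmax(floor(gx / px) + 1L, 1L), nx)
  iy <- pmin(pmax(floor(gy / px) + 1L, 1L), ny)
  hits <- sum(mask_obj$mask[ix, iy])
  point_grid(a_p = spacing_um^2, hits_astro = hits,
             total_points = length(ix) * length(iy),
             spacing = spacing_um)
}
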