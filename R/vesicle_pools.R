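# Vesicle perimeter analysis: minimum membrane-to-membrane distance from each
# synaptic vesicle to the presynaptic active zone (PreAZ), classification into
# the functionally defined pools, and per-bouton vesicle statistics.
#
# The perimeter p of a vesicle is (distance from vesicle centre to the PreAZ
# surface) - diameter/2: negative values mean membrane overlap/fusion.

#' Analytic PreAZ patches and triangle meshes
#'
#' In reconstruction mode the PreAZ surface is the triangulated ribbon mesh
#' extracted from the bouton membrane; in synthetic mode it is an analytic
#' patch (infinite/disc plane or spherical cap) with closed-form distances.
#' All three satisfy the same distance contract.
#'
#' @param origin point on the plane (length-3, nm)
#' @param normal plane normal (need not be unit length)
#' @param radius patch radius about `origin` within the plane; `Inf` for an
#'   unbounded plane
#' @return object of class `az_surface`
#' @rdname az_surface
#' @export
az_plane <- function(origin = c(0, 0, 0), normal = c(0, 0, 1), radius = Inf) {
  normal <- normal / sqrt(sum(normal^2))
  structure(list(type = "plane", origin = origin, normal = normal,
                 radius = radius),
            class = "az_surface")
}

#' @param center sphere centre (nm)
#' @param R sphere radius (nm)
#' @param axis cap axis direction (from centre towards the cap pole)
#' @param theta cap half-angle, radians
#' @rdname az_surface
#' @export
az_cap <- function(center, R, axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  stopifnot(R > 0, theta > 0, theta <= pi)
  structure(list(type = "cap", center = center, R = R, axis = axis,
                 theta = theta),
            class = "az_surface")
}

#' @param triangles n x 9 matrix, one triangle per row
#'   (x1,y1,z1,x2,y2,z2,x3,y3,z3), nm
#' @rdname az_surface
#' @export
az_mesh <- function(triangles) {
  triangles <- as.matrix(triangles)
  stopifnot(ncol(triangles) == 9, nrow(triangles) >= 1)
  structure(list(type = "mesh", triangles = triangles), class = "az_surface")
}

# ---- closed-form / mesh distances (centre to surface, nm) ----

dist_to_plane <- function(pts, az) {
  d <- sweep(pts, 2, az$origin)
  ax <- as.numeric(d %*% az$normal)
  if (is.infinite(az$radius)) return(abs(ax))
  # radial distance within the plane
  inplane <- d - outer(ax, az$normal)
  r <- sqrt(rowSums(inplane^2))
  inside <- r <= az$radius
  out <- sqrt(pmax(0, r - az$radius)^2 + ax^2)
  ifelse(inside, abs(ax), out)
}

dist_to_cap <- function(pts, az) {
  d <- sweep(pts, 2, az$center)
  rho <- sqrt(rowSums(d^2))
  ca <- as.numeric(d %*% az$axis) / pmax(rho, .Machine$double.eps)
  alpha <- acos(pmin(1, pmax(-1, ca)))
  under <- alpha <= az$theta
  # nearest rim point lies in the plane spanned by axis and the query point
  rim <- sqrt(rho^2 + az$R^2 - 2 * rho * az$R * cos(alpha - az$theta))
  ifelse(under, abs(az$R - rho), rim)
}

# Point-to-triangle distances, vectorised over triangles. The minimum over
# (i) the in-plane projection when it falls inside the triangle and (ii) the
# three clamped point-to-edge distances is exact.
dist_to_mesh <- function(pts, az) {
  tr <- az$triangles
  A <- tr[, 1:3, drop = FALSE]
  E0 <- tr[, 4:6, drop = FALSE] - A
  E1 <- tr[, 7:9, drop = FALSE] - A
  E2 <- E1 - E0                       # edge from vertex B to vertex C
  a <- rowSums(E0 * E0); b <- rowSums(E0 * E1); c <- rowSums(E1 * E1)
  det <- pmax(a * c - b * b, .Machine$double.eps)
  eps <- .Machine$double.eps
  seg_q <- function(D, E, EE) {
    tt <- pmin(pmax(-rowSums(D * E) / pmax(EE, eps), 0), 1)
    rowSums((D + tt * E)^2)
  }
  e2e2 <- rowSums(E2 * E2)
  apply_one <- function(p) {
    D <- sweep(A, 2, p)               # vertex A relative to the point
    d <- rowSums(E0 * D); e <- rowSums(E1 * D)
    s <- (b * e - c * d) / det
    t <- (b * d - a * e) / det
    inside <- s >= 0 & t >= 0 & (s + t) <= 1
    q <- seg_q(D, E0, a)                       # edge A-B
    q <- pmin(q, seg_q(D, E1, c))              # edge A-C
    q <- pmin(q, seg_q(D + E0, E2, e2e2))      # edge B-C
    if (any(inside)) {
      qi <- rowSums((D + s * E0 + t * E1)^2)
      q[inside] <- pmin(q[inside], qi[inside])
    }
    sqrt(max(min(q), 0))
  }
  vapply(seq_len(nrow(pts)), function(i) apply_one(pts[i, ]), numeric(1))
}

#' Minimum membrane distance of vesicles to the PreAZ
#'
#' For each vesicle, the minimum Euclidean distance from its centre to the
#' PreAZ surface minus its radius: the membrane-to-membrane perimeter p.
#' Negative values indicate membrane overlap (docking/fusion); p can never
#' be below `-diameter`.
#'
#' @param centers n x 3 matrix of vesicle centres (nm), or length-3 vector
#' @param diameters vesicle diameters (nm), recycled to n
#' @param az an `az_surface` (plane, cap, or triangle mesh)
#' @return numeric vector of perimeters p (nm)
#' @export
min_membrane_distance <- function(centers, diameters, az) {
  stopifnot(inherits(az, "az_surface"))
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 3)
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 3)
  d <- switch(az$type,
              plane = dist_to_plane(centers, az),
              cap = dist_to_cap(centers, az),
              mesh = dist_to_mesh(centers, az),
              stop("unknown az surface type"))
  p <- d - rep_len(diameters, nrow(centers)) / 2
  pmax(p, -rep_len(diameters, nrow(centers)))
}

#' Classify vesicles into functional pools
#'
#' Pools by perimeter p (nm): the putative readily releasable pool at the
#' p10 (`p <= 10`) and cumulative p20 (`p <= 20`) criteria, an explicitly
#' reported unassigned band (20, 60), the recycling pool `[60, 200]`, and
#' the resting pool (> 200, with the > = 500 nm tail reported separately).
#' Boundary values belong to the named pool. Docked vesicles are those in
#' membrane contact, `p <= 0`.
#'
#' @param p numeric vector of perimeters (nm), e.g. from
#'   [min_membrane_distance()]
#' @param thresholds strictly increasing pool boundaries
#'   (default `c(10, 20, 60, 200, 500)`)
#' @return object of class `pool_counts`
#' @export
classify_pools <- function(p, thresholds = c(10, 20, 60, 200, 500)) {
  stopifnot(length(thresholds) == 5, all(diff(thresholds) > 0))
  th <- thresholds
  counts <- list(
    n_total = length(p),
    rrp_p10 = sum(p <= th[1]),
    rrp_p20 = sum(p <= th[2]),
    unassigned_20_60 = sum(p > th[2] & p < th[3]),
    rp_60_200 = sum(p >= th[3] & p <= th[4]),
    resting_gt200 = sum(p > th[4]),
    resting_gt500 = sum(p >= th[5]),
    docked = sum(p <= 0)
  )
  out <- structure(counts, class = "pool_counts")
  stopifnot(out$rrp_p10 <= out$rrp_p20,
            out$rrp_p20 + out$unassigned_20_60 + out$rp_60_200 +
              out$resting_gt200 == out$n_total,
            out$resting_gt500 <= out$resting_gt200,
            out$docked <= out$rrp_p10)
  out
}

#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf(paste0("<pool_counts> n=%d  p10=%d p20=%d unassigned=%d ",
                     "rp=%d resting=%d (>500: %d)  docked=%d\n"),
              x$n_total, x$rrp_p10, x$rrp_p20, x$unassigned_20_60,
              x$rp_60_200, x$resting_gt200, x$resting_gt500, x$docked))
  invisible(x)
}

#' Docked-vesicle count
#'
#' The geometric surrogate for tomographically identified docked vesicles:
#' membrane contact or overlap with the PreAZ, i.e. `p <= 0`.
#'
#' @param p vector of perimeters (nm)
#' @return integer count
#' @export
docked_count <- function(p) sum(p <= 0)

#' Vesicle descriptive statistics for one bouton
#'
#' Diameter summaries per vesicle type, the total volume of the small clear
#' vesicles (spheres of the recorded diameter; dense-core vesicles excluded)
#' and its percentage of the bouton volume.
#'
#' @param vesicles data.frame with columns `diameter_nm` and `vtype`
#' @param bouton_volume bouton volume in um^3 (> 0 for the percentage)
#' @return list with `diameter_stats` (named list of [describe()] per vtype),
#'   `sv_volume_um3`, `sv_percent_of_bouton`
#' @export
vesicle_stats <- function(vesicles, bouton_volume) {
  if (bouton_volume <= 0) stop("undefined percentage: bouton_volume must be > 0")
  sv <- vesicles$diameter_nm[vesicles$vtype == "SV"]
  vol <- nm3_to_um3(sum(pi * sv^3 / 6))
  stats <- lapply(split(vesicles$diameter_nm, vesicles$vtype), describe)
  list(diameter_stats = stats,
       sv_volume_um3 = vol,
       sv_percent_of_bouton = 100 * vol / bouton_volume)
}
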