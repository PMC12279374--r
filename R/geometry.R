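# Reconstruction geometry: planar areas, section-sum volumes, ribbon-meshed
# surfaces, active-zone areas and derived measures. Inputs are in nm; all
# reported areas are um^2 and volumes um^3.

#' Area of a simple polygon
#'
#' Shoelace area of an implicitly closed polygon; orientation-independent.
#'
#' @param xy two-column vertex matrix, nm
#' @param check if TRUE (default), reject self-intersecting polygons;
#'   internal callers that have already validated the stack pass FALSE
#' @return area in nm^2
#' @export
polygon_area <- function(xy, check = TRUE) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n > 1 && all(xy[1, ] == xy[n, ])) { xy <- xy[-n, , drop = FALSE]; n <- n - 1L }
  if (n < 3) stop("polygon_area: need >= 3 vertices")
  if (check && !polygon_is_simple(xy))
    stop("geometry error: self-intersecting polygon")
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Simplicity test: no two non-adjacent edges intersect.
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 4) return(TRUE)
  j <- c(2:n, 1)
  p1x <- xy[, 1]; p1y <- xy[, 2]
  p2x <- xy[j, 1]; p2y <- xy[j, 2]
  idx <- which(outer(seq_len(n), seq_len(n), function(a, b) b > a + 1 &
                       !(a == 1 & b == n)), arr.ind = TRUE)
  if (nrow(idx) == 0) return(TRUE)
  a <- idx[, 1]; b <- idx[, 2]
  d1 <- cross2(p2x[a] - p1x[a], p2y[a] - p1y[a], p1x[b] - p1x[a], p1y[b] - p1y[a])
  d2 <- cross2(p2x[a] - p1x[a], p2y[a] - p1y[a], p2x[b] - p1x[a], p2y[b] - p1y[a])
  d3 <- cross2(p2x[b] - p1x[b], p2y[b] - p1y[b], p1x[a] - p1x[b], p1y[a] - p1y[b])
  d4 <- cross2(p2x[b] - p1x[b], p2y[b] - p1y[b], p2x[a] - p1x[b], p2y[a] - p1y[b])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

cross2 <- function(ax, ay, bx, by) ax * by - ay * bx

polyline_length <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2) return(0)
  sum(sqrt(rowSums(diff(xy)^2)))
}

stack_section_areas <- function(stack, check = FALSE) {
  sec <- sections_of(stack)
  areas <- vapply(stack$contours, function(ct) polygon_area(ct$xy, check = check),
                  numeric(1))
  a <- tapply(areas, sec, sum)
  data.frame(section = as.integer(names(a)), area = as.numeric(a))
}

# Fill missing interior sections by linear interpolation of area.
interpolate_gaps <- function(df) {
  full <- seq(min(df$section), max(df$section))
  miss <- setdiff(full, df$section)
  if (length(miss) == 0) return(list(df = df, interpolated = integer()))
  area <- stats::approx(df$section, df$area, xout = full)$y
  list(df = data.frame(section = full, area = area), interpolated = miss)
}

#' Volume of a reconstructed object
#'
#' Section-sum (Cavalieri-type) volume: the planar contour area of every
#' section multiplied by the section thickness, summed over the stack.
#' Missing interior sections are linearly interpolated in area with a
#' warning.
#'
#' @param stack a validated [contour_stack()] with an area-bearing label
#' @return volume in um^3
#' @export
stack_volume <- function(stack) {
  stopifnot(inherits(stack, "contour_stack"))
  if (!stack$label %in% AREA_LABELS)
    stop("geometry error: stack_volume needs an area-bearing label, got '",
         stack$label, "'")
  df <- stack_section_areas(stack)
  gi <- interpolate_gaps(df)
  if (length(gi$interpolated))
    warning(sprintf("stack '%s': interpolated area for missing section(s) %s",
                    stack$object_id,
                    paste(gi$interpolated, collapse = ", ")))
  nm3_to_um3(sum(gi$df$area) * stack$meta$section_thickness)
}

# Resample an implicitly closed polygon to m points equally spaced along its
# arc length, preserving counter-clockwise orientation.
resample_closed <- function(xy, m = 64L) {
  n <- nrow(xy)
  if (signed_area(xy) < 0) xy <- xy[n:1, , drop = FALSE]
  pts <- rbind(xy, xy[1, ])
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  if (L == 0) return(matrix(rep(xy[1, ], each = m), ncol = 2))
  s <- (seq_len(m) - 1) / m * L
  cbind(stats::approx(cum, pts[, 1], xout = s)$y,
        stats::approx(cum, pts[, 2], xout = s)$y)
}

signed_area <- function(xy) {
  n <- nrow(xy); j <- c(2:n, 1)
  sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]) / 2
}

tri_area3 <- function(a, b, c) {
  u <- b - a; v <- c - a
  w <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  sqrt(rowSums(w^2)) / 2
}

# Ribbon between two rings (m x 2 each) separated by dz; correspondence by
# the cyclic offset minimising total squared distance (minimal twist).
ribbon_area <- function(p, q, dz) {
  m <- nrow(p)
  best <- Inf; bestk <- 0L
  pc <- sweep(p, 2, colMeans(p)); qc <- sweep(q, 2, colMeans(q))
  for (k in 0:(m - 1)) {
    idx <- ((seq_len(m) - 1 + k) %% m) + 1
    d <- sum((pc - qc[idx, ])^2)
    if (d < best) { best <- d; bestk <- k }
  }
  idx <- ((seq_len(m) - 1 + bestk) %% m) + 1
  q <- q[idx, , drop = FALSE]
  nxt <- c(2:m, 1)
  P <- cbind(p, 0); Q <- cbind(q, dz)
  sum(tri_area3(P, Q, Q[nxt, , drop = FALSE])) +
    sum(tri_area3(P, Q[nxt, , drop = FALSE], P[nxt, , drop = FALSE]))
}

#' Surface area of a reconstructed object
#'
#' Triangulated lateral bands between consecutive contours (arc-length
#' resampling to a common vertex count, nearest-centroid correspondence,
#' minimal-twist cyclic alignment) plus the two planar end caps. A
#' single-section stack uses the closed-slab convention
#' `2 * area + perimeter * t`.
#'
#' @param stack a validated [contour_stack()] with an area-bearing label
#' @param n_resample vertices per resampled ring (default 64)
#' @return surface area in um^2
#' @export
stack_surface_area <- function(stack, n_resample = 64L) {
  stopifnot(inherits(stack, "contour_stack"))
  if (!stack$label %in% AREA_LABELS)
    stop("geometry error: stack_surface_area needs an area-bearing label")
  t_nm <- stack$meta$section_thickness
  sec <- sections_of(stack)
  if (anyDuplicated(sec))
    stop(sprintf("geometry error: stack '%s' has multiple contours in section(s) %s (branching object)",
                 stack$object_id,
                 paste(unique(sec[duplicated(sec)]), collapse = ", ")))
  ord <- order(sec)
  cts <- stack$contours[ord]; sec <- sec[ord]
  if (length(cts) == 1) {
    a <- polygon_area(cts[[1]]$xy, check = FALSE)
    xy <- cts[[1]]$xy
    per <- polyline_length(rbind(xy, xy[1, ]))
    return(nm2_to_um2(2 * a + per * t_nm))
  }
  rings <- lapply(cts, function(ct) resample_closed(ct$xy, n_resample))
  lateral <- 0
  for (i in seq_len(length(rings) - 1)) {
    dz <- (sec[i + 1] - sec[i]) * t_nm
    lateral <- lateral + ribbon_area(rings[[i]], rings[[i + 1]], dz)
  }
  # contours sit on section mid-planes: the object extends half a section
  # beyond the outermost contours, closed by a prism band plus the end caps
  perim <- function(ct) polyline_length(rbind(ct$xy, ct$xy[1, ]))
  ends <- (perim(cts[[1]]) + perim(cts[[length(cts)]])) * t_nm / 2
  caps <- polygon_area(cts[[1]]$xy, check = FALSE) +
    polygon_area(cts[[length(cts)]]$xy, check = FALSE)
  nm2_to_um2(lateral + ends + caps)
}

#' Morphometry of a set of stacks
#'
#' Convenience wrapper running [stack_volume()] and [stack_surface_area()]
#' over a list of stacks.
#'
#' @param stacks list of [contour_stack()]
#' @return data.frame with `object_id, label, volume_um3, surface_um2,
#'   n_sections`
#' @export
morphometry <- function(stacks) {
  stacks <- Filter(function(s) s$label %in% AREA_LABELS, stacks)
  do.call(rbind, lapply(stacks, function(st) data.frame(
    object_id = st$object_id, label = st$label,
    volume_um3 = stack_volume(st),
    surface_um2 = stack_surface_area(st),
    n_sections = length(st$contours),
    stringsAsFactors = FALSE)))
}

#' Presynaptic active-zone membrane area
#'
#' The PreAZ is annotated as open polylines, one per section, following the
#' presynaptic membrane specialization. Its surface area is the triangulated
#' ribbon between consecutive polylines (arc-length resampled to a common
#' vertex count): for straight polylines stacked vertically this reduces to
#' the trapezoid `mean(length_i, length_(i+1)) * dz`, and on curved
#' membranes it additionally captures the local slant. A single-section zone
#' contributes `length * t`. The representative length `l_preaz` (used by
#' the PSD perimeter-ratio formula) is the mean per-section polyline length.
#'
#' @param preaz_lines list of entries `list(section =, xy =)` with open
#'   polyline vertices in nm (several polylines per section allowed; their
#'   lengths add, and the area falls back to the trapezoid rule)
#' @param t section thickness, nm
#' @return list with `sa_preaz` (um^2) and `l_preaz` (um)
#' @export
preaz_surface_area <- function(preaz_lines, t, n_resample = 33L) {
  if (length(preaz_lines) == 0) stop("need >= 1 polyline")
  sec <- vapply(preaz_lines, function(p) as.integer(p$section), integer(1))
  len <- vapply(preaz_lines, function(p) polyline_length(p$xy), numeric(1))
  if (any(len == 0)) stop("zero-length polyline")
  L <- tapply(len, sec, sum)
  s <- as.integer(names(L)); L <- as.numeric(L)
  ord <- order(s); s <- s[ord]; L <- L[ord]
  one_per_section <- !anyDuplicated(sec)
  sa <- if (length(L) == 1) {
    L * t
  } else if (!one_per_section) {
    sum((L[-1] + L[-length(L)]) / 2 * diff(s) * t)
  } else {
    o <- order(vapply(preaz_lines, function(p) p$section, numeric(1)))
    lines <- lapply(preaz_lines[o], function(p)
      resample_open(as.matrix(p$xy), n_resample))
    a <- 0
    for (i in seq_len(length(lines) - 1)) {
      P <- lines[[i]]; Q <- lines[[i + 1]]
      # orient consistently: endpoints may be traced in opposite directions
      if (sum((P[1, ] - Q[1, ])^2) + sum((P[nrow(P), ] - Q[nrow(Q), ])^2) >
          sum((P[1, ] - Q[nrow(Q), ])^2) + sum((P[nrow(P), ] - Q[1, ])^2))
        Q <- Q[nrow(Q):1, , drop = FALSE]
      dz <- (s[i + 1] - s[i]) * t
      P3 <- cbind(P, 0); Q3 <- cbind(Q, dz)
      m <- nrow(P3); idx <- seq_len(m - 1)
      a <- a + sum(tri_area3(P3[idx, , drop = FALSE],
                             Q3[idx, , drop = FALSE],
                             Q3[idx + 1, , drop = FALSE])) +
        sum(tri_area3(P3[idx, , drop = FALSE], Q3[idx + 1, , drop = FALSE],
                      P3[idx + 1, , drop = FALSE]))
    }
    a
  }
  list(sa_preaz = nm2_to_um2(sa), l_preaz = mean(L) * 1e-3)
}

#' PSD area from the perimeter ratio
#'
#' The postsynaptic density runs parallel to the PreAZ across the cleft, so
#' its area is estimated by scaling the PreAZ area with the ratio of the two
#' contour-line lengths: `sa_psd = sa_preaz * l_psd / l_preaz`.
#'
#' @param sa_preaz PreAZ surface area (um^2, >= 0)
#' @param l_psd,l_preaz representative contour-line lengths (um); both must
#'   use the same per-section convention
#' @return PSD surface area, um^2
#' @export
psd_area_from_ratio <- function(sa_preaz, l_psd, l_preaz) {
  if (any(c(sa_preaz, l_psd, l_preaz) < 0)) stop("inputs must be >= 0")
  if (l_preaz == 0) stop("undefined ratio: l_preaz = 0")
  sa_preaz * l_psd / l_preaz
}

#' Synaptic cleft width measurement
#'
#' One cleft is measured at its two lateral edges and at the central region;
#' the lateral values are averaged per measurement (cohort aggregation is
#' left to the statistics module).
#'
#' @param lateral_left,lateral_right,central widths in nm, all >= 0
#' @return object of class `cleft_measure` with `lateral_mean` derived
#' @export
cleft_width <- function(lateral_left, lateral_right, central) {
  if (any(c(lateral_left, lateral_right, central) < 0))
    stop("cleft widths must be >= 0")
  structure(list(lateral_left = lateral_left, lateral_right = lateral_right,
                 central = central,
                 lateral_mean = (lateral_left + lateral_right) / 2),
            class = "cleft_measure")
}

#' Mitochondrial volume fraction of a bouton
#'
#' @param bouton_volume bouton volume, um^3 (> 0)
#' @param mito_volumes numeric vector of mitochondrial volumes, um^3
#'   (may be empty: boutons with no mitochondria score 0)
#' @return percentage of the bouton volume occupied by mitochondria
#' @export
mito_volume_fraction <- function(bouton_volume, mito_volumes = numeric()) {
  if (bouton_volume <= 0)
    stop("undefined fraction: bouton volume must be > 0")
  100 * sum(mito_volumes) / bouton_volume
}
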