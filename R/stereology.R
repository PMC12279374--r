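# Design-based stereology: unbiased counting frame, physical disector
# synapse density, Cavalieri point-count volume estimation and astrocytic
# coverage classification.

#' Unbiased counting frame
#'
#' A rectangle with two inclusion edges (left, bottom) and two exclusion
#' edges (right, top). Objects inside the frame or touching an inclusion
#' edge are counted; objects touching an exclusion edge or its extension
#' (the full lines `x = x0 + w`, `y = y0 + h`) are rejected, which makes the
#' sampling unbiased.
#'
#' @param x0,y0 lower-left corner (um)
#' @param width,height frame dimensions (um, > 0)
#' @return object of class `counting_frame`
#' @export
counting_frame <- function(x0, y0, width, height) {
  stopifnot(width > 0, height > 0)
  structure(list(x0 = x0, y0 = y0, x1 = x0 + width, y1 = y0 + height,
                 area = width * height),
            class = "counting_frame")
}

#' Apply the counting-frame rule
#'
#' @param objects data.frame with centroid columns `x`, `y` and optionally
#'   `extent` (half-width of the object's bounding box; defaults to 0, i.e.
#'   point objects)
#' @param frame a [counting_frame()]
#' @return the included subset of `objects`
#' @export
counting_frame_filter <- function(objects, frame) {
  stopifnot(inherits(frame, "counting_frame"))
  e <- objects$extent %||% rep(0, nrow(objects))
  overlaps <- (objects$x + e) >= frame$x0 & (objects$x - e) < frame$x1 &
    (objects$y + e) >= frame$y0 & (objects$y - e) < frame$y1
  touches_exclusion <- (objects$x + e) >= frame$x1 | (objects$y + e) >= frame$y1
  objects[overlaps & !touches_exclusion, , drop = FALSE]
}

#' Physical-disector sample
#'
#' A set of reference/look-up section pairs sharing one counting frame and
#' section thickness. Objects are labelled centroids with persistent ids, so
#' disappearance between the sections of a pair is established by id.
#'
#' @param frame a [counting_frame()]
#' @param thickness_t section thickness, um (> 0)
#' @param pairs list of `list(reference =, lookup =)` data.frames, each with
#'   columns `id`, `x`, `y` (and optional `extent`)
#' @return object of class `dissector_sample`
#' @export
dissector_sample <- function(frame, thickness_t, pairs) {
  stopifnot(inherits(frame, "counting_frame"), thickness_t > 0)
  structure(list(frame = frame, thickness_t = thickness_t, pairs = pairs),
            class = "dissector_sample")
}

#' Disector counts
#'
#' For each reference/look-up pair, the number of objects that pass the
#' counting-frame rule in the reference section and are absent (by id) from
#' the look-up section: the object "tops" the disector volume.
#'
#' @param sample a [dissector_sample()]
#' @param strict if TRUE, look-up sections containing ids never seen in any
#'   reference section of the sample raise an integrity error
#' @return list with per-pair counts `qd` and their total `sum_qd`
#' @export
dissector_count <- function(sample, strict = FALSE) {
  stopifnot(inherits(sample, "dissector_sample"))
  if (strict) {
    ref_ids <- unique(unlist(lapply(sample$pairs,
                                    function(p) p$reference$id)))
    for (p in sample$pairs) {
      stray <- setdiff(p$lookup$id, ref_ids)
      if (length(stray))
        stop("integrity error: look-up ids unmatched in reference sections: ",
             paste(utils::head(stray, 5), collapse = ", "))
    }
  }
  qd <- vapply(sample$pairs, function(p) {
    kept <- counting_frame_filter(p$reference, sample$frame)
    sum(!(kept$id %in% p$lookup$id))
  }, numeric(1))
  list(qd = qd, sum_qd = sum(qd))
}

#' Synapse density from disector counts
#'
#' `Nv = sum(Qd) / sum(Vd)` with the disector volume
#' `Vd = n_dissectors * frame_area * thickness`, reported per mm^3.
#'
#' @param sum_qd total disector count (>= 0)
#' @param n_dissectors number of section pairs (> 0)
#' @param frame_area counting-frame area, um^2 (> 0)
#' @param thickness_t section thickness, um (> 0)
#' @return density in synapses per mm^3
#' @export
density_nv <- function(sum_qd, n_dissectors, frame_area, thickness_t) {
  if (n_dissectors <= 0 || frame_area <= 0 || thickness_t <= 0)
    stop("disector volume must be > 0")
  if (sum_qd < 0) stop("sum_qd must be >= 0")
  sum_qd / (n_dissectors * frame_area * thickness_t) * 1e9
}

#' Point grid for Cavalieri estimation
#'
#' @param a_p area associated with one grid point, um^2 (> 0); the default
#'   0.64 um^2 corresponds to 0.8 x 0.8 um grid squares. (The counting
#'   protocol is sometimes described with a 1 x 1 um overlay; the a(p)
#'   entering the estimator is the 0.8 x 0.8 um square, which is what the
#'   volume formula uses. Configure `a_p` to match your grid.)
#' @param hits_astro points hitting astrocytic profiles, per section
#'   (scalar or vector)
#' @param total_points points applied per section (scalar or vector,
#'   aligned with `hits_astro`)
#' @param spacing grid spacing, um (metadata; default `sqrt(a_p)`)
#' @return object of class `point_grid`
#' @export
point_grid <- function(a_p = 0.64, hits_astro, total_points,
                       spacing = sqrt(a_p)) {
  stopifnot(a_p > 0)
  hits_astro <- as.numeric(hits_astro)
  total_points <- rep_len(as.numeric(total_points), length(hits_astro))
  if (any(hits_astro < 0) || any(hits_astro > total_points))
    stop("need 0 <= hits_astro <= total_points")
  structure(list(a_p = a_p, spacing = spacing, hits_astro = hits_astro,
                 total_points = total_points),
            class = "point_grid")
}

#' Cavalieri point-count estimate
#'
#' Volume fraction as the percentage of grid points hitting astrocytic
#' profiles, and the absolute volume `V = a(p) * sum(P) * t` summed over the
#' sections sampled.
#'
#' @param grid a [point_grid()] with per-section hit counts
#' @param thickness_t section thickness, um
#' @return list with `fraction_percent` and `volume_um3`
#' @export
cavalieri_volume <- function(grid, thickness_t) {
  stopifnot(inherits(grid, "point_grid"), thickness_t > 0)
  tp <- sum(grid$total_points)
  if (tp == 0) stop("total_points must be > 0")
  hits <- sum(grid$hits_astro)
  list(fraction_percent = 100 * hits / tp,
       volume_um3 = grid$a_p * hits * thickness_t)
}

#' Astrocytic coverage class of one active zone
#'
#' Fine astrocytic processes reaching the synaptic cleft on both flanks of
#' the AZ, on exactly one, or on neither.
#'
#' @param left_reaches_cleft,right_reaches_cleft logical flank annotations
#' @param target postsynaptic target, "spine" or "shaft"
#' @param az_id optional identifier
#' @return data.frame row with `az_id`, `target`, `klass` in
#'   `{both_sides, one_side, none}`
#' @export
classify_az_coverage <- function(left_reaches_cleft, right_reaches_cleft,
                                 target = c("spine", "shaft"),
                                 az_id = NA_character_) {
  target <- match.arg(target)
  if (is.na(left_reaches_cleft) || is.na(right_reaches_cleft))
    stop("missing flank annotation")
  n_sides <- left_reaches_cleft + right_reaches_cleft
  klass <- c("none", "one_side", "both_sides")[n_sides + 1]
  data.frame(az_id = az_id, target = target, klass = klass,
             stringsAsFactors = FALSE)
}

#' Coverage summary table
#'
#' Percentages of AZs per coverage class and postsynaptic target; when a
#' `patient_id` column is present, percentages are computed per patient and
#' reported as mean +- SD across patients.
#'
#' @param records data.frame with columns `target`, `klass` and optionally
#'   `patient_id`
#' @return data.frame with columns `target`, `klass`, `percent` (and
#'   `sd_percent`, `n_patients` when grouped by patient)
#' @export
coverage_summary <- function(records) {
  stopifnot(nrow(records) >= 1)
  klasses <- c("both_sides", "one_side", "none")
  stopifnot(all(records$klass %in% klasses))
  one <- function(df) {
    tab <- table(factor(df$klass, klasses))
    100 * as.numeric(tab) / nrow(df)
  }
  per_target <- function(df, target) {
    if (!is.null(df$patient_id) && length(unique(df$patient_id)) > 1) {
      by_pat <- t(vapply(split(df, df$patient_id), one, numeric(3)))
      data.frame(target = target, klass = klasses,
                 percent = colMeans(by_pat),
                 sd_percent = apply(by_pat, 2, stats::sd),
                 n_patients = nrow(by_pat), stringsAsFactors = FALSE)
    } else {
      data.frame(target = target, klass = klasses, percent = one(df),
                 stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, lapply(split(records, records$target),
                               function(df) per_target(df, df$target[1])))
  rownames(out) <- NULL
  out
}
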