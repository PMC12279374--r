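#' @importFrom jsonlite read_json toJSON
#' @importFrom utils read.csv write.csv
NULL

AREA_LABELS <- c("bouton", "mitochondrion", "spine", "shaft", "astrocyte")
LINE_LABELS <- c("preaz_line", "psd_line")
KNOWN_LABELS <- c(AREA_LABELS, LINE_LABELS)

#' Series metadata
#'
#' Describes one serial-section annotation series: identification, sublamina,
#' section thickness (the `t` used by all volume and disector formulas) and
#' pixel size. All coordinates handled by this package are in nanometres; the
#' z position of a contour is `section_index * section_thickness`, taken as
#' the section mid-plane.
#'
#' @param series_id,patient_id character identifiers (patients are coded)
#' @param sublamina one of "L1a", "L1b", "other"
#' @param section_thickness section thickness in nm (> 0; 50 nm default)
#' @param pixel_size nm per pixel of the source micrographs (metadata only)
#' @param n_sections number of sections in the series (>= 1)
#' @return object of class `series_meta`
#' @export
series_meta <- function(series_id = "series-1", patient_id = "p0",
                        sublamina = c("other", "L1a", "L1b"),
                        section_thickness = 50, pixel_size = 1,
                        n_sections = 1L) {
  sublamina <- match.arg(sublamina, c("L1a", "L1b", "other"))
  if (!is.numeric(section_thickness) || section_thickness <= 0)
    stop("section_thickness must be > 0 (nm)")
  if (n_sections < 1) stop("n_sections must be >= 1")
  structure(list(series_id = as.character(series_id),
                 patient_id = as.character(patient_id),
                 sublamina = sublamina,
                 section_thickness = as.numeric(section_thickness),
                 pixel_size = as.numeric(pixel_size),
                 n_sections = as.integer(n_sections)),
            class = "series_meta")
}

#' Single-section contour
#'
#' One closed polygon (area-bearing labels) or open polyline (`preaz_line`,
#' `psd_line`) drawn on one section. Polygons are implicitly closed: the
#' first vertex is not repeated at the end.
#'
#' @param section_index 0-based section index
#' @param xy two-column numeric matrix of vertices, nm
#' @param label structure label
#' @param object_id id of the reconstructed object the contour belongs to
#' @return object of class `contour`
#' @export
contour <- function(section_index, xy, label, object_id) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2) stop("xy must be a two-column matrix")
  storage.mode(xy) <- "double"
  # canonicalize explicit closure
  n <- nrow(xy)
  if (n > 1 && all(xy[1, ] == xy[n, ])) xy <- xy[-n, , drop = FALSE]
  if (section_index < 0) stop("section_index must be >= 0")
  min_v <- if (label %in% LINE_LABELS) 2L else 3L
  if (nrow(xy) < min_v)
    stop(sprintf("label '%s' needs >= %d vertices, got %d",
                 label, min_v, nrow(xy)))
  structure(list(section_index = as.integer(section_index),
                 xy = unname(xy),
                 label = as.character(label),
                 object_id = as.character(object_id)),
            class = "contour")
}

#' Contour stack: one reconstructed object
#'
#' A z-ordered collection of contours sharing one `object_id` and label,
#' together with the series metadata that fixes the section thickness.
#'
#' @param object_id object identifier
#' @param label shared structure label
#' @param contours list of [contour()] objects
#' @param meta a [series_meta()]
#' @return object of class `contour_stack`
#' @export
contour_stack <- function(object_id, label, contours, meta) {
  stopifnot(inherits(meta, "series_meta"), length(contours) >= 1)
  lab <- vapply(contours, `[[`, "", "label")
  oid <- vapply(contours, `[[`, "", "object_id")
  if (!all(lab == label) || !all(oid == object_id))
    stop(sprintf("stack '%s': contours with mismatching label/object_id",
                 object_id))
  sec <- vapply(contours, `[[`, integer(1), "section_index")
  contours <- contours[order(sec)]
  structure(list(object_id = as.character(object_id),
                 label = as.character(label),
                 contours = contours, meta = meta),
            class = "contour_stack")
}

#' @export
print.contour_stack <- function(x, ...) {
  sec <- sections_of(x)
  cat(sprintf("<contour_stack> %s [%s], %d contour(s), sections %d..%d, t = %g nm\n",
              x$object_id, x$label, length(x$contours),
              min(sec), max(sec), x$meta$section_thickness))
  invisible(x)
}

sections_of <- function(stack)
  vapply(stack$contours, `[[`, integer(1), "section_index")

#' Validate a contour stack
#'
#' Report-only structural checks: self-intersecting polygons, duplicate or
#' non-monotone section indices, gaps (missing interior sections) and
#' degenerate vertex counts. Never throws; downstream geometry refuses
#' stacks whose report contains errors.
#'
#' @param stack a [contour_stack()]
#' @return data.frame with columns `severity` ("error"/"warning"),
#'   `section`, `message`; zero rows for a clean stack
#' @export
validate_stack <- function(stack) {
  stopifnot(inherits(stack, "contour_stack"))
  issues <- list()
  add <- function(severity, section, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, section = as.integer(section),
      message = message, stringsAsFactors = FALSE)
  sec <- sections_of(stack)
  dup <- sec[duplicated(sec)]
  for (s in unique(dup))
    add("error", s, sprintf("duplicate contour in section %d", s))
  if (length(sec) > 1) {
    gaps <- which(diff(sort(unique(sec))) > 1)
    su <- sort(unique(sec))
    for (g in gaps)
      add("warning", su[g + 1], sprintf("gap before section %d", su[g + 1]))
  }
  is_area <- stack$label %in% AREA_LABELS
  for (ct in stack$contours) {
    if (is_area) {
      if (nrow(ct$xy) < 3) {
        add("error", ct$section_index,
            sprintf("section %d: polygon with < 3 vertices",
                    ct$section_index))
      } else if (!polygon_is_simple(ct$xy)) {
        add("error", ct$section_index,
            sprintf("self-intersection at section %d", ct$section_index))
      }
    } else {
      if (nrow(ct$xy) < 2)
        add("error", ct$section_index,
            sprintf("section %d: polyline with < 2 vertices",
                    ct$section_index))
      if (any(rowSums(abs(diff(ct$xy))) == 0) && nrow(ct$xy) == 2)
        add("error", ct$section_index,
            sprintf("section %d: zero-length polyline", ct$section_index))
    }
  }
  if (length(issues) == 0)
    return(data.frame(severity = character(), section = integer(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

canon_num <- function(x) round(x, 2)  # declared precision: 0.01 nm

#' Write an annotation series
#'
#' Serialises metadata and contour stacks to a self-describing JSON container
#' and, when vesicle records are supplied (possibly zero rows), a CSV sidecar
#' `<path minus .json>_vesicles.csv`. Coordinates are canonicalised to 0.01 nm
#' so that write -> read -> write is byte-identical.
#'
#' @param meta a [series_meta()]
#' @param stacks list of [contour_stack()]
#' @param vesicles NULL or a data.frame with columns
#'   `vesicle_id, bouton_id, x_nm, y_nm, z_nm, diameter_nm, vtype`
#' @param path output path (".json")
#' @return `path`, invisibly
#' @export
write_series <- function(meta, stacks, vesicles = NULL, path) {
  stopifnot(inherits(meta, "series_meta"))
  for (st in stacks) {
    rep <- validate_stack(st)
    if (any(rep$severity == "error"))
      stop(sprintf("stack '%s' fails validation: %s", st$object_id,
                   rep$message[rep$severity == "error"][1]))
  }
  if (!is.null(vesicles)) check_vesicles(vesicles, stacks)
  js <- list(
    meta = list(series_id = meta$series_id, patient_id = meta$patient_id,
                sublamina = meta$sublamina,
                section_thickness = meta$section_thickness,
                pixel_size = meta$pixel_size,
                n_sections = meta$n_sections),
    stacks = lapply(stacks, function(st) list(
      object_id = st$object_id, label = st$label,
      contours = lapply(st$contours, function(ct) list(
        section = ct$section_index,
        xy = canon_num(ct$xy)))))
  )
  txt <- jsonlite::toJSON(js, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  writeLines(txt, path)
  if (!is.null(vesicles)) {
    vp <- vesicle_sidecar_path(path)
    v <- vesicles[, c("vesicle_id", "bouton_id", "x_nm", "y_nm", "z_nm",
                      "diameter_nm", "vtype"), drop = FALSE]
    num <- c("x_nm", "y_nm", "z_nm", "diameter_nm")
    v[num] <- lapply(v[num], canon_num)
    utils::write.csv(v, vp, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

vesicle_sidecar_path <- function(path)
  paste0(sub("\\.json$", "", path), "_vesicles.csv")

check_vesicles <- function(vesicles, stacks) {
  need <- c("vesicle_id", "bouton_id", "x_nm", "y_nm", "z_nm",
            "diameter_nm", "vtype")
  miss <- setdiff(need, names(vesicles))
  if (length(miss))
    stop("vesicle table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(vesicles) == 0) return(invisible(TRUE))
  if (any(vesicles$diameter_nm <= 0))
    stop("vesicle diameters must be > 0")
  if (!all(vesicles$vtype %in% c("SV", "DCV")))
    stop("vtype must be 'SV' or 'DCV'")
  bids <- vapply(stacks, `[[`, "", "object_id")
  blabs <- vapply(stacks, `[[`, "", "label")
  boutons <- bids[blabs == "bouton"]
  bad <- setdiff(unique(vesicles$bouton_id), boutons)
  if (length(bad))
    stop("integrity error: vesicle bouton_id not matching any bouton stack: ",
         paste(utils::head(bad, 5), collapse = ", "))
  sv <- vesicles$vtype == "SV"
  out <- sv & (vesicles$diameter_nm < 10 | vesicles$diameter_nm > 60)
  if (any(out))
    warning(sprintf("%d SV diameter(s) outside the plausible 10-60 nm range",
                    sum(out)))
  invisible(TRUE)
}

#' Read an annotation series
#'
#' Parses the JSON container written by [write_series()] (and its vesicle CSV
#' sidecar if present), rebuilding typed objects and enforcing referential
#' integrity: every vesicle's `bouton_id` must name a bouton stack.
#'
#' @param path path to the series JSON
#' @return list with elements `meta` ([series_meta()]), `stacks`
#'   (list of [contour_stack()]) and `vesicles` (data.frame, zero rows when
#'   no sidecar exists)
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  m <- js$meta
  meta <- series_meta(m$series_id %||% "series-1", m$patient_id %||% "p0",
                      m$sublamina %||% "other",
                      m$section_thickness %||% 50,
                      m$pixel_size %||% 1, m$n_sections %||% 1L)
  stacks <- lapply(js$stacks, function(st) {
    cts <- lapply(st$contours, function(ct) {
      xy <- do.call(rbind, lapply(ct$xy, function(p) unlist(p)))
      if (is.null(xy) || ncol(xy) != 2)
        stop(sprintf("parse error: malformed geometry in object '%s' section %s",
                     st$object_id, ct$section %||% "?"))
      contour(ct$section, xy, st$label, st$object_id)
    })
    contour_stack(st$object_id, st$label, cts, meta)
  })
  vp <- vesicle_sidecar_path(path)
  vesicles <- if (file.exists(vp)) {
    utils::read.csv(vp, stringsAsFactors = FALSE)
  } else {
    data.frame(vesicle_id = character(), bouton_id = character(),
               x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
               diameter_nm = numeric(), vtype = character(),
               stringsAsFactors = FALSE)
  }
  if (nrow(vesicles)) check_vesicles(vesicles, stacks)
  list(meta = meta, stacks = stacks, vesicles = vesicles)
}
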