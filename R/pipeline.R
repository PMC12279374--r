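# End-to-end pipeline: validate -> reconstruct -> pools -> report, with a
# YAML-configurable entry point shared by run_pipeline() and the synstereo
# command-line script.

#' Build the PreAZ ribbon mesh from annotation polylines
#'
#' Resamples each section's polyline to a common vertex count and
#' triangulates the band between consecutive sections; a single-section zone
#' is extruded symmetrically by the section thickness. Used for
#' reconstruction-mode vesicle distances.
#'
#' @param stack a [contour_stack()] with label `preaz_line`
#' @param n_resample vertices per resampled polyline
#' @return an `az_surface` mesh
#' @export
preaz_mesh <- function(stack, n_resample = 33L) {
  stopifnot(inherits(stack, "contour_stack"))
  t <- stack$meta$section_thickness
  sec <- sections_of(stack)
  ord <- order(sec); sec <- sec[ord]
  lines <- lapply(stack$contours[ord], function(ct)
    resample_open(ct$xy, n_resample))
  tri <- list()
  strip <- function(P, Q) {
    m <- nrow(P); nxt <- 2:m
    rbind(cbind(P[nxt - 1, ], Q[nxt - 1, ], Q[nxt, ]),
          cbind(P[nxt - 1, ], Q[nxt, ], P[nxt, ]))
  }
  if (length(lines) == 1) {
    P <- cbind(lines[[1]], sec[1] * t - t / 2)
    Q <- cbind(lines[[1]], sec[1] * t + t / 2)
    tri[[1]] <- strip(P, Q)
  } else {
    for (i in seq_len(length(lines) - 1)) {
      P <- cbind(lines[[i]], sec[i] * t)
      Q <- cbind(lines[[i + 1]], sec[i + 1] * t)
      tri[[i]] <- strip(P, Q)
    }
  }
  az_mesh(do.call(rbind, tri))
}

resample_open <- function(xy, m = 33L) {
  seg <- sqrt(rowSums(diff(xy)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  s <- seq(0, L, length.out = m)
  cbind(stats::approx(cum, xy[, 1], xout = s)$y,
        stats::approx(cum, xy[, 2], xout = s)$y)
}

#' Pool classification for every bouton of a series
#'
#' Computes vesicle perimeters against each bouton's PreAZ and classifies
#' them into pools. The PreAZ surface is taken from `az` (analytic patches,
#' e.g. straight from the generator) when supplied, otherwise triangulated
#' from the `preaz_line` stacks whose object id starts with the bouton id.
#'
#' @param series list with `stacks` and `vesicles` as returned by
#'   [read_series()] or [generate_bouton_cohort()]
#' @param az optional named list of `az_surface` objects keyed by bouton id
#' @param thresholds pool boundaries, nm
#' @return data.frame, one row per bouton, with the pool counts
#' @export
pools_from_series <- function(series, az = NULL,
                              thresholds = c(10, 20, 60, 200, 500)) {
  labs <- vapply(series$stacks, `[[`, "", "label")
  ids <- vapply(series$stacks, `[[`, "", "object_id")
  boutons <- ids[labs == "bouton"]
  rows <- lapply(boutons, function(bid) {
    v <- series$vesicles[series$vesicles$bouton_id == bid &
                           series$vesicles$vtype == "SV", , drop = FALSE]
    surface <- if (!is.null(az) && !is.null(az[[bid]])) {
      az[[bid]]
    } else {
      pre <- which(labs == "preaz_line" & startsWith(ids, bid))
      if (length(pre) == 0)
        stop("no PreAZ annotation for bouton ", bid)
      preaz_mesh(series$stacks[[pre[1]]])
    }
    p <- if (nrow(v)) {
      min_membrane_distance(cbind(v$x_nm, v$y_nm, v$z_nm), v$diameter_nm,
                            surface)
    } else numeric()
    pc <- classify_pools(p, thresholds)
    data.frame(bouton_id = bid, n_total = pc$n_total, rrp_p10 = pc$rrp_p10,
               rrp_p20 = pc$rrp_p20, unassigned = pc$unassigned_20_60,
               rp = pc$rp_60_200, resting = pc$resting_gt200,
               resting_gt500 = pc$resting_gt500, docked = pc$docked,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pipeline configuration
#'
#' @param profile cohort profile name or YAML path (simulation input)
#' @param input path to a series JSON (annotation input; exactly one of
#'   `profile`/`input` must be given)
#' @param out_dir output directory for the CSV artifacts
#' @param seed integer seed for simulation
#' @param n_boutons cohort size override (NULL = profile value)
#' @param thresholds strictly increasing pool boundaries, nm
#' @param a_p Cavalieri area per point, um^2
#' @param frame_um disector counting-frame side, um
#' @param n_pairs disector pairs
#' @param thickness_um section thickness for stereology, um
#' @return validated object of class `pipeline_config`
#' @export
pipeline_config <- function(profile = NULL, input = NULL, out_dir = "out",
                            seed = 1L, n_boutons = NULL,
                            thresholds = c(10, 20, 60, 200, 500),
                            a_p = 0.64, frame_um = 9, n_pairs = 20,
                            thickness_um = 0.05) {
  if (is.null(profile) == is.null(input))
    stop("config error: give exactly one of 'profile' or 'input'")
  if (length(thresholds) != 5 || any(diff(thresholds) <= 0))
    stop("config error: thresholds must be strictly increasing")
  if (any(c(a_p, frame_um, n_pairs, thickness_um) <= 0))
    stop("config error: physical parameters must be > 0")
  structure(list(profile = profile, input = input, out_dir = out_dir,
                 seed = as.integer(seed), n_boutons = n_boutons,
                 thresholds = thresholds, a_p = a_p, frame_um = frame_um,
                 n_pairs = n_pairs, thickness_um = thickness_um),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected (fail fast) so that typos cannot silently fall
#' back to defaults.
#'
#' @param path YAML file
#' @return a [pipeline_config()]
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), "")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, x)
}

#' Run the full pipeline
#'
#' Simulation mode (config with `profile`): generates the cohort, then
#' validates every stack, reconstructs morphometry, classifies vesicle
#' pools, summarises astrocytic coverage, estimates the disector synapse
#' density at the profile's calibrated density, and writes the report
#' tables. Annotation mode (config with `input`): same, minus the
#' generator-only stages (coverage, density).
#'
#' Outputs written to `out_dir`: `morpho.csv`, `pools.csv`, `coverage.csv`
#' (simulation mode), `report.csv`, and `run_manifest.json` recording the
#' package version, seed and configuration.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a list with the in-memory tables and `status` 0
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  simulate <- !is.null(config$profile)
  if (simulate) {
    prof <- load_profile(config$profile)
    series <- generate_bouton_cohort(
      prof, seed = config$seed,
      n_boutons = config$n_boutons %||% prof$n_boutons)
    az <- series$az
  } else {
    series <- read_series(config$input)
    az <- NULL
  }
  bad <- list()
  for (st in series$stacks) {
    rep <- validate_stack(st)
    if (any(rep$severity == "error")) bad[[st$object_id]] <- rep
  }
  if (length(bad))
    stop("validation failure in stack(s): ",
         paste(names(bad), collapse = ", "))
  morpho <- morphometry(series$stacks)
  pools <- pools_from_series(series, az = az,
                             thresholds = config$thresholds)
  values <- data.frame(
    parameter = rep(c("n_total", "rrp_p10", "rrp_p20", "rp", "resting"),
                    each = nrow(pools)),
    group = series$meta$sublamina,
    value = c(pools$n_total, pools$rrp_p10, pools$rrp_p20, pools$rp,
              pools$resting), stringsAsFactors = FALSE)
  vols <- morpho[morpho$label == "bouton", ]
  values <- rbind(values, data.frame(parameter = "bouton_volume_um3",
                                     group = series$meta$sublamina,
                                     value = vols$volume_um3,
                                     stringsAsFactors = FALSE))
  report <- build_report(values)
  utils::write.csv(morpho, file.path(config$out_dir, "morpho.csv"),
                   row.names = FALSE)
  utils::write.csv(pools, file.path(config$out_dir, "pools.csv"),
                   row.names = FALSE)
  utils::write.csv(report, file.path(config$out_dir, "report.csv"),
                   row.names = FALSE)
  cov <- NULL
  if (simulate) {
    recs <- data.frame(az_id = series$manifest$boutons$bouton_id,
                       target = series$manifest$boutons$target,
                       klass = series$manifest$boutons$coverage,
                       stringsAsFactors = FALSE)
    cov <- coverage_summary(recs)
    utils::write.csv(cov, file.path(config$out_dir, "coverage.csv"),
                     row.names = FALSE)
  }
  manifest <- list(package = "synstereo",
                   version = as.character(utils::packageVersion("synstereo")),
                   seed = config$seed,
                   config = unclass(config))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(config$out_dir, "run_manifest.json"))
  invisible(list(status = 0L, morpho = morpho, pools = pools,
                 report = report, coverage = cov))
}
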