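# Per-patient measurement chain and cohort analysis: volume QC ->
# superimposition -> cranial frame -> condylar and symphyseal metrics ->
# airway volumes and CSA profiles -> percentage changes; then descriptive
# summaries, one-tailed Spearman hypothesis tests and optional reliability.

#' Pipeline configuration
#'
#' @param landmarks a [landmark_set()] (in pre-operative mesh coordinates).
#' @param regions named list of region specifications (frame coordinates):
#'   `skull_mask` (ICP mask), `condyle_left`, `condyle_right`, `symphysis`.
#' @param airway named list of plane z-offsets along frame Z: `top`,
#'   `naso_oro`, `e_plane`, `bottom` (strictly decreasing).
#' @param qc list: `tolerance` (relative volume difference, default 0.02)
#'   and optional `region` specification of the stable structure compared.
#' @param post_crop_margin mm by which post-operative crop regions are
#'   expanded to cover the expected displacement (default 20).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(landmarks, regions, airway,
                            qc = list(tolerance = 0.02, region = NULL),
                            post_crop_margin = 20) {
  stopifnot(all(c("condyle_left", "condyle_right", "symphysis") %in%
                  names(regions)),
            all(c("top", "naso_oro", "e_plane", "bottom") %in% names(airway)))
  if (!inherits(landmarks, "landmark_set")) landmarks <- landmark_set(landmarks)
  structure(list(landmarks = landmarks, regions = regions,
                 airway = airway, qc = qc,
                 post_crop_margin = post_crop_margin),
            class = "pipeline_config")
}

#' Configuration matching the phantom layout
#'
#' @return A [pipeline_config()] whose landmarks, crop regions and airway
#'   plane offsets are the [phantom_geometry()] constants.
#' @export
phantom_config <- function() {
  g <- phantom_geometry()
  pipeline_config(landmarks = g$landmarks, regions = g$regions,
                  airway = g$airway[c("top", "naso_oro", "e_plane", "bottom")])
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a [pipeline_config()].
#' @param path a `.json` path.
#' @return `write_pipeline_config`: `path` invisibly;
#'   `read_pipeline_config`: a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  obj <- list(landmarks = lapply(unclass(config$landmarks), as.numeric),
              regions = config$regions, airway = config$airway,
              qc = config$qc, post_crop_margin = config$post_crop_margin)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  qc <- obj$qc %||% list(tolerance = 0.02, region = NULL)
  if (is.null(qc$tolerance)) qc$tolerance <- 0.02
  pipeline_config(landmarks = landmark_set(obj$landmarks),
                  regions = obj$regions, airway = obj$airway, qc = qc,
                  post_crop_margin = obj$post_crop_margin %||% 20)
}

#' A per-patient case
#'
#' @param id unique patient identifier.
#' @param pre_skull,post_skull,pre_airway,post_airway bone and airway-lumen
#'   meshes at the two timepoints: STL file paths or [surface_mesh()]
#'   objects.
#' @param config a [pipeline_config()] or a JSON path.
#' @param metadata optional named list of covariates.
#' @return Object of class `patient_case`.
#' @export
patient_case <- function(id, pre_skull, post_skull, pre_airway, post_airway,
                         config, metadata = list()) {
  meshes <- list(pre_skull = pre_skull, post_skull = post_skull,
                 pre_airway = pre_airway, post_airway = post_airway)
  for (nm in names(meshes)) {
    m <- meshes[[nm]]
    if (is.character(m)) {
      if (!file.exists(m)) stop("case '", id, "': missing file for ", nm, ": ", m)
    } else stopifnot(inherits(m, "surface_mesh"))
  }
  if (is.character(config)) {
    if (!file.exists(config)) stop("case '", id, "': missing config ", config)
  } else stopifnot(inherits(config, "pipeline_config"))
  structure(c(list(id = id), meshes,
              list(config = config, metadata = metadata)),
            class = "patient_case")
}

expand_region <- function(spec, margin) {
  switch(spec$type,
         box = list(type = "box", min = as.numeric(spec$min) - margin,
                    max = as.numeric(spec$max) + margin),
         sphere = list(type = "sphere", center = spec$center,
                       radius = spec$radius + margin),
         spec)
}

exclusion <- function(id, reason, call = NULL) {
  stop(structure(class = c("airwaymorph_exclusion", "error", "condition"),
                 list(message = paste0("case '", id, "' excluded: ", reason),
                      reason = reason, id = id, call = call)))
}

resolve_mesh <- function(x) if (is.character(x)) read_stl(x, quiet = TRUE) else x

#' Run the full measurement chain for one patient
#'
#' Stage sequence: segmentation volume QC, ICP superimposition of the
#' post-operative bone mesh on the pre-operative cranium (masked to the
#' surgically unchanged region), cranial-frame construction from landmarks,
#' per-condyle rigid pose fits, symphysis centre-point deviation in the
#' midsagittal plane, airway segment volumes and 1 mm CSA profiles, and
#' percentage changes. Deterministic for fixed inputs.
#'
#' @param case a [patient_case()].
#' @param stages subset of
#'   `c("qc", "register", "condyles", "symphysis", "airway_volumes",
#'   "airway_csa")`; the cranial frame is always built. Dropping stages
#'   yields `NA` for their metrics (used to bound cohort-simulation cost).
#' @return A one-row data frame of all metrics (class `patient_record`),
#'   with attribute `warnings` collecting stage warnings.
#' @export
run_patient <- function(case, stages = c("qc", "register", "condyles",
                                         "symphysis", "airway_volumes",
                                         "airway_csa")) {
  stopifnot(inherits(case, "patient_case"))
  cfg <- if (is.character(case$config)) read_pipeline_config(case$config)
         else case$config
  warn <- character(0)
  wcollect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
  })
  pre_bone <- resolve_mesh(case$pre_skull)
  post_bone <- resolve_mesh(case$post_skull)
  pre_air <- resolve_mesh(case$pre_airway)
  post_air <- resolve_mesh(case$post_airway)
  rec <- list(id = case$id)

  if ("qc" %in% stages) {
    qc <- tryCatch(wcollect(volume_qc(pre_bone, post_bone,
                                      tolerance = cfg$qc$tolerance %||% 0.02,
                                      region = cfg$qc$region)),
                   error = function(e) exclusion(case$id, conditionMessage(e)))
    rec$qc_ratio <- qc$ratio
    if (!qc$pass) exclusion(case$id, "segmentation volume mismatch")
  } else rec$qc_ratio <- NA_real_

  if ("register" %in% stages) {
    reg <- tryCatch(wcollect(register_icp(post_bone, pre_bone,
                                          mask_region = cfg$regions$skull_mask)),
                    error = function(e)
                      exclusion(case$id, paste0("registration failed: ",
                                                conditionMessage(e))))
    rec$icp_rms <- reg$rms
    post_bone <- transform_apply(reg$transform, post_bone)
    post_air <- transform_apply(reg$transform, post_air)
  } else rec$icp_rms <- NA_real_

  frame <- build_frame(cfg$landmarks)
  pre_bone <- to_frame(pre_bone, frame); post_bone <- to_frame(post_bone, frame)
  pre_air <- to_frame(pre_air, frame); post_air <- to_frame(post_air, frame)
  margin <- cfg$post_crop_margin %||% 20

  cond_fields <- c("dX", "dY", "dZ", "dXY", "dXZ", "dYZ", "dXYZ",
                   "phi_x", "theta_y", "psi_z")
  for (side in c("left", "right")) {
    pfx <- if (side == "left") "L_" else "R_"
    if ("condyles" %in% stages) {
      spec <- cfg$regions[[paste0("condyle_", side)]]
      res <- tryCatch(wcollect({
        pre_c <- crop_region(pre_bone, spec)
        post_c <- crop_region(post_bone, expand_region(spec, margin))
        tr <- fit_region_transform(pre_c, post_c)
        condyle_displacement(tr, colMeans(pre_c$vertices), side)
      }), error = function(e)
        exclusion(case$id, paste0(side, " condyle fit failed: ",
                                  conditionMessage(e))))
      for (f in cond_fields) rec[[paste0(pfx, f)]] <- res[[f]]
    } else for (f in cond_fields) rec[[paste0(pfx, f)]] <- NA_real_
  }

  if ("symphysis" %in% stages) {
    spec <- cfg$regions$symphysis
    sd_ <- tryCatch(wcollect({
      pre_s <- crop_region(pre_bone, spec)
      post_s <- crop_region(post_bone, expand_region(spec, margin))
      symphysis_deviation(pre_s, post_s, plane3d(c(0, 0, 0), c(0, 1, 0)))
    }), error = function(e)
      exclusion(case$id, paste0("symphysis deviation failed: ",
                                conditionMessage(e))))
    rec$S_dX <- sd_$s_dx; rec$S_dZ <- sd_$s_dz; rec$S_dXZ <- sd_$s_dxz
  } else { rec$S_dX <- rec$S_dZ <- rec$S_dXZ <- NA_real_ }

  need_air <- any(c("airway_volumes", "airway_csa") %in% stages)
  if (need_air) {
    az <- cfg$airway
    zp <- function(z) plane3d(c(0, 0, z), c(0, 0, 1))
    planes <- airway_planes(zp(az$top), zp(az$naso_oro), zp(az$e_plane),
                            zp(az$bottom))
  }
  vol_fields <- c("naso", "oro", "hypo", "total")
  if ("airway_volumes" %in% stages) {
    vres <- tryCatch(wcollect({
      vp <- airway_volumes(pre_air, planes, "pre")
      vq <- airway_volumes(post_air, planes, "post")
      list(vp = vp, vq = vq, ch = airway_change(vp, vq))
    }), error = function(e)
      exclusion(case$id, paste0("airway volumes failed: ",
                                conditionMessage(e))))
    for (f in vol_fields) {
      rec[[paste0("vol_", f, "_pre")]] <- vres$vp[[f]]
      rec[[paste0("vol_", f, "_post")]] <- vres$vq[[f]]
      rec[[paste0(f, "_pct")]] <- unname(vres$ch$volume_pct[f])
    }
  } else for (f in vol_fields) {
    rec[[paste0("vol_", f, "_pre")]] <- NA_real_
    rec[[paste0("vol_", f, "_post")]] <- NA_real_
    rec[[paste0(f, "_pct")]] <- NA_real_
  }
  if ("airway_csa" %in% stages) {
    cres <- tryCatch(wcollect({
      pp <- csa_profile(pre_air, planes)
      pq <- csa_profile(post_air, planes)
      list(pp = pp, pq = pq)
    }), error = function(e)
      exclusion(case$id, paste0("CSA profile failed: ", conditionMessage(e))))
    rec$min_csa_oro_pre <- cres$pp$min_csa_oro
    rec$min_csa_oro_post <- cres$pq$min_csa_oro
    rec$min_csa_hypo_pre <- cres$pp$min_csa_hypo
    rec$min_csa_hypo_post <- cres$pq$min_csa_hypo
    rec$min_csa_oro_pct <- 100 * cres$pq$min_csa_oro / cres$pp$min_csa_oro
    rec$min_csa_hypo_pct <- 100 * cres$pq$min_csa_hypo / cres$pp$min_csa_hypo
  } else {
    for (f in c("min_csa_oro_pre", "min_csa_oro_post", "min_csa_hypo_pre",
                "min_csa_hypo_post", "min_csa_oro_pct", "min_csa_hypo_pct"))
      rec[[f]] <- NA_real_
  }
  out <- as.data.frame(rec, stringsAsFactors = FALSE)
  class(out) <- c("patient_record", class(out))
  attr(out, "warnings") <- warn
  out
}

#' Default hypothesis grid
#'
#' The antero-posterior deviation sources (`R_dX`, `L_dX`, `S_dX`) crossed
#' with the airway outcomes (segment and total volume percentages, oro- and
#' hypopharyngeal minCSA percentages), all one-tailed positive: anterior
#' deviation is expected to go with larger airway, posterior with smaller.
#'
#' @return Data frame with columns `source`, `outcome`, `direction`.
#' @export
default_hypotheses <- function() {
  expand.grid(source = c("L_dX", "R_dX", "S_dX"),
              outcome = c("naso_pct", "oro_pct", "hypo_pct", "total_pct",
                          "min_csa_oro_pct", "min_csa_hypo_pct"),
              direction = "positive", stringsAsFactors = FALSE)
}

#' Run the cohort analysis
#'
#' Runs [run_patient()] for every case (failures become logged exclusions;
#' the run continues), then computes per-metric descriptive summaries
#' (median, IQR) and the configured one-tailed Spearman tests. Accounting
#' closure holds by construction: cases in = records out + exclusions.
#'
#' @param cases list of [patient_case()] objects with unique ids.
#' @param hypotheses data frame `source`/`outcome`/`direction` (default
#'   [default_hypotheses()]).
#' @param stages passed to [run_patient()].
#' @param icc_repeats optional list of two data frames of repeated
#'   measurements (same variables, same subjects) for the reliability table.
#' @param p_adjust `"none"` (default, matching the un-adjusted analysis) or
#'   `"BH"` for Benjamini-Hochberg.
#' @return Object of class `cohort_results`: `records`, `exclusions`,
#'   `descriptives`, `correlations`, `icc` (or `NULL`), `n_in`.
#' @export
run_cohort <- function(cases, hypotheses = default_hypotheses(),
                       stages = c("qc", "register", "condyles", "symphysis",
                                  "airway_volumes", "airway_csa"),
                       icc_repeats = NULL, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  ids <- vapply(cases, function(cs) cs$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate patient ids: ", paste(unique(ids[duplicated(ids)]),
                                          collapse = ", "))
  records <- list(); excl <- list()
  for (cs in cases) {
    r <- tryCatch(run_patient(cs, stages = stages),
                  airwaymorph_exclusion = function(e)
                    structure(list(id = e$id, reason = e$reason),
                              class = "am_excl"),
                  error = function(e)
                    structure(list(id = cs$id, reason = conditionMessage(e)),
                              class = "am_excl"))
    if (inherits(r, "am_excl"))
      excl[[length(excl) + 1L]] <- data.frame(id = r$id, reason = r$reason)
    else records[[length(records) + 1L]] <- r
  }
  if (length(records) < 4L)
    stop("fewer than 4 usable patient records (", length(records), ")")
  records <- do.call(rbind, records)
  exclusions <- if (length(excl)) do.call(rbind, excl)
                else data.frame(id = character(0), reason = character(0))
  num <- names(records)[vapply(records, is.numeric, TRUE)]
  num <- num[colSums(!is.na(records[num])) > 0]
  descriptives <- do.call(rbind, lapply(num, function(v) {
    d <- describe(records[[v]][!is.na(records[[v]])])
    data.frame(metric = v, median = d[["median"]], q25 = d[["q25"]],
               q75 = d[["q75"]], n = sum(!is.na(records[[v]])))
  }))
  correlations <- NULL
  if (!is.null(hypotheses) && nrow(hypotheses)) {
    rows <- lapply(seq_len(nrow(hypotheses)), function(i) {
      h <- hypotheses[i, ]
      if (!all(c(h$source, h$outcome) %in% names(records))) return(NULL)
      xs <- records[[h$source]]; ys <- records[[h$outcome]]
      ok <- !is.na(xs) & !is.na(ys)
      if (sum(ok) < 4L) return(NULL)
      ct <- spearman_one_tailed(xs[ok], ys[ok], direction = h$direction)
      data.frame(source = h$source, outcome = h$outcome,
                 direction = h$direction, n = ct$n, rho = ct$rho,
                 p_one_tailed = ct$p_one_tailed)
    })
    correlations <- do.call(rbind, rows)
    if (!is.null(correlations) && p_adjust == "BH")
      correlations$p_adjusted <- stats::p.adjust(correlations$p_one_tailed,
                                                 method = "BH")
  }
  icc <- if (!is.null(icc_repeats))
    icc_table(icc_repeats[[1]], icc_repeats[[2]]) else NULL
  structure(list(records = records, exclusions = exclusions,
                 descriptives = descriptives, correlations = correlations,
                 icc = icc, n_in = length(cases)),
            class = "cohort_results")
}

#' @export
print.cohort_results <- function(x, ...) {
  cat(sprintf("<cohort_results> %d cases in = %d records + %d exclusions\n",
              x$n_in, nrow(x$records), nrow(x$exclusions)))
  if (!is.null(x$correlations) && nrow(x$correlations)) {
    cat("correlations (one-tailed Spearman):\n")
    print(x$correlations, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Build an in-memory case from a phantom truth
#'
#' @param truth a [phantom_truth()].
#' @param id case identifier.
#' @return A [patient_case()] with generated meshes and [phantom_config()].
#' @export
phantom_case <- function(truth, id = "phantom") {
  bone <- make_bone_phantom(truth)
  air <- make_airway_phantom(truth)
  patient_case(id = id, pre_skull = bone$pre, post_skull = bone$post,
               pre_airway = air$pre, post_airway = air$post,
               config = phantom_config())
}

#' Run a full synthetic-cohort simulation
#'
#' Generates a cohort from the specification, measures every subject through
#' the pipeline stages requested, and runs the cohort analysis. The default
#' stages measure exactly what the setback/minCSA hypothesis needs
#' (symphysis sectioning and CSA profiles), which keeps a 35-subject cohort
#' at a few seconds.
#'
#' @param spec a [cohort_spec()].
#' @param stages passed to [run_patient()].
#' @param hypotheses passed to [run_cohort()]; default tests `S_dX` against
#'   the hypopharyngeal minCSA percentage change, one-tailed positive.
#' @param ... passed to [make_cohort()] (phantom resolution).
#' @return A `cohort_results` object with the generator `truth_table`
#'   attached.
#' @export
run_phantom_cohort <- function(spec,
                               stages = c("symphysis", "airway_csa"),
                               hypotheses = data.frame(
                                 source = "S_dX",
                                 outcome = "min_csa_hypo_pct",
                                 direction = "positive",
                                 stringsAsFactors = FALSE),
                               ...) {
  coh <- make_cohort(spec, ...)
  cases <- lapply(seq_along(coh$truths), function(i)
    phantom_case(coh$truths[[i]], id = coh$table$id[i]))
  res <- run_cohort(cases, hypotheses = hypotheses, stages = stages)
  res$truth_table <- coh$table
  res
}

#' Write cohort results as CSV files
#'
#' Schema-stable outputs: `records.csv` (one row per patient; mm, degrees,
#' mm^2, mm^3 and percentages), `descriptives.csv`, `correlations.csv`,
#' `exclusions.csv`, and `icc.csv` when reliability was computed.
#'
#' @param results a `cohort_results` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
cohort_to_csv <- function(results, dir) {
  stopifnot(inherits(results, "cohort_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(results$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(results$descriptives, file.path(dir, "descriptives.csv"),
                   row.names = FALSE)
  if (!is.null(results$correlations))
    utils::write.csv(results$correlations, file.path(dir, "correlations.csv"),
                     row.names = FALSE)
  utils::write.csv(results$exclusions, file.path(dir, "exclusions.csv"),
                   row.names = FALSE)
  if (!is.null(results$icc))
    utils::write.csv(results$icc$table, file.path(dir, "icc.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Tidy CSA profile table
#'
#' @param profile an [csa_profile()] result.
#' @param patient,timepoint identifiers added as columns.
#' @return Data frame `patient`, `timepoint`, `segment`, `offset_mm`,
#'   `area_mm2`.
#' @export
tidy_profile <- function(profile, patient = "", timepoint = "") {
  cbind(data.frame(patient = patient, timepoint = timepoint),
        profile$profile)
}

#' Plot pre/post CSA profiles
#'
#' Area against signed offset from the E-plane (positive cranial), pre and
#' post overlaid.
#'
#' @param pre_profile,post_profile [csa_profile()] results.
#' @param ... passed to [plot()].
#' @return Invisibly `NULL`; draws on the active device.
#' @export
plot_profile <- function(pre_profile, post_profile = NULL, ...) {
  p <- pre_profile$profile
  ylim <- range(p$area_mm2, if (!is.null(post_profile))
    post_profile$profile$area_mm2)
  plot(p$offset_mm, p$area_mm2, type = "l", col = "steelblue4", lwd = 2,
       xlab = "offset from E-plane (mm, + cranial)",
       ylab = expression(area ~ (mm^2)), ylim = ylim, ...)
  if (!is.null(post_profile))
    graphics::lines(post_profile$profile$offset_mm,
                    post_profile$profile$area_mm2, col = "firebrick", lwd = 2)
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topright", legend = c("pre", "post")[1:(1 + !is.null(post_profile))],
                   col = c("steelblue4", "firebrick"), lwd = 2, bty = "n")
  invisible(NULL)
}
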