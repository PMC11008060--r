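# Upper-airway segmentation by reference planes (naso-/oro-/hypopharynx),
# segment volumes, percentage change, and 1 mm cross-sectional-area profiles
# from the E-plane (epiglottis plane) with minCSA detection.

#' Airway reference planes
#'
#' Four planes ordered cranio-caudally, all with cranially oriented normals:
#' `top` (nasopharynx superior bound), `naso_oro` (naso/oropharynx
#' boundary), `e_plane` (epiglottis plane, oro/hypopharynx boundary) and
#' `bottom` (hypopharynx inferior bound).
#'
#' @param top,naso_oro,e_plane,bottom [plane3d()] objects.
#' @return Object of class `airway_planes`.
#' @export
airway_planes <- function(top, naso_oro, e_plane, bottom) {
  pl <- list(top = top, naso_oro = naso_oro, e_plane = e_plane, bottom = bottom)
  stopifnot(all(vapply(pl, inherits, TRUE, "plane3d")))
  n <- e_plane$normal
  dots <- vapply(pl, function(p) sum(p$normal * n), numeric(1))
  if (any(dots < 0.99))
    stop("airway planes must share a cranial normal orientation ",
         "(pairwise deviation > ~8 degrees)")
  off <- vapply(pl, function(p) sum((p$point - e_plane$point) * n), numeric(1))
  if (!all(diff(off) < 0))
    stop("airway planes out of order: signed offsets must decrease strictly ",
         "from top to bottom (got ", paste(sprintf("%.2f", off), collapse = ", "), ")")
  structure(c(pl, list(offsets = off, axis = n)), class = "airway_planes")
}

#' @export
print.airway_planes <- function(x, ...) {
  cat(sprintf("<airway_planes> offsets from E-plane (mm): top %.1f, naso_oro %.1f, e_plane %.1f, bottom %.1f\n",
              x$offsets[1], x$offsets[2], x$offsets[3], x$offsets[4]))
  invisible(x)
}

# kept-slab clip for one named segment; normals flipped to point inward
clip_segment <- function(lumen, lower_plane, upper_plane, segment) {
  lo <- plane3d(lower_plane$point, lower_plane$normal)        # cranial normal
  up <- plane3d(upper_plane$point, -upper_plane$normal)       # flipped caudal
  tryCatch(clip_between_planes(lumen, lo, up),
           error = function(e)
             stop("empty segment '", segment, "': ", conditionMessage(e)))
}

#' Split the airway lumen into naso-, oro- and hypopharynx
#'
#' Clips the lumen between consecutive reference planes; the three watertight
#' segments partition the lumen between the top and bottom planes.
#'
#' @param lumen a watertight [surface_mesh()] of the airway lumen.
#' @param planes an [airway_planes()] set.
#' @return Named list of `surface_mesh`: `naso`, `oro`, `hypo`.
#' @export
segment_airway <- function(lumen, planes) {
  stopifnot(inherits(planes, "airway_planes"))
  list(naso = clip_segment(lumen, planes$naso_oro, planes$top, "naso"),
       oro  = clip_segment(lumen, planes$e_plane, planes$naso_oro, "oro"),
       hypo = clip_segment(lumen, planes$bottom, planes$e_plane, "hypo"))
}

#' Airway segment volumes
#'
#' @param lumen a watertight [surface_mesh()].
#' @param planes an [airway_planes()] set.
#' @param timepoint `"pre"` or `"post"`.
#' @return Object of class `airway_volumes`: `naso`, `oro`, `hypo`, `total`
#'   (mm^3) and `timepoint`.
#' @export
airway_volumes <- function(lumen, planes, timepoint = c("pre", "post")) {
  timepoint <- match.arg(timepoint)
  segs <- segment_airway(lumen, planes)
  v <- vapply(segs, mesh_volume, numeric(1))
  if (any(v < 1e-9))
    warning("zero-length or degenerate airway segment: ",
            paste(names(v)[v < 1e-9], collapse = ", "))
  out <- list(naso = v[["naso"]], oro = v[["oro"]], hypo = v[["hypo"]],
              total = sum(v), timepoint = timepoint)
  class(out) <- "airway_volumes"
  out
}

#' @export
print.airway_volumes <- function(x, ...) {
  cat(sprintf("<airway_volumes> [%s] naso %.1f, oro %.1f, hypo %.1f, total %.1f mm^3\n",
              x$timepoint, x$naso, x$oro, x$hypo, x$total))
  invisible(x)
}

#' Cross-sectional area profile from the E-plane
#'
#' Sections the lumen with planes parallel to the E-plane at `spacing`
#' (default 1 mm) intervals: cranially through the oropharynx up to (strictly
#' below) the naso/oro boundary, caudally through the hypopharynx down to
#' (strictly above) the bottom plane. Offsets are signed: positive cranial
#' (oropharynx), negative caudal (hypopharynx). The E-plane itself (offset 0)
#' is book-kept with the hypopharynx, but the oropharyngeal minimum also
#' considers it; both minima are reported with their offsets so the
#' convention is auditable.
#'
#' @param lumen a [surface_mesh()].
#' @param planes an [airway_planes()] set.
#' @param spacing sampling interval in mm (default 1).
#' @param area_mode `"sum"` (even-odd holes; a lumen split around the
#'   epiglottis is counted correctly) or `"largest"`.
#' @return Object of class `airway_profile`: data frame `profile` (`segment`,
#'   `offset_mm`, `area_mm2`), plus `min_csa_oro`, `min_csa_hypo` and their
#'   offsets `min_offset_oro`, `min_offset_hypo`.
#' @export
csa_profile <- function(lumen, planes, spacing = 1.0,
                        area_mode = c("sum", "largest")) {
  area_mode <- match.arg(area_mode)
  stopifnot(inherits(planes, "airway_planes"), spacing > 0)
  n <- planes$axis
  e0 <- sum(planes$e_plane$point * n)
  up_extent <- planes$offsets[["naso_oro"]]
  dn_extent <- planes$offsets[["bottom"]]
  ks_up <- seq_len(max(0, ceiling(up_extent / spacing) - 1L)) * spacing
  ks_up <- ks_up[ks_up < up_extent - 1e-9]
  ks_dn <- -seq_len(max(0, ceiling(-dn_extent / spacing) - 1L)) * spacing
  ks_dn <- ks_dn[ks_dn > dn_extent + 1e-9]
  offsets <- c(sort(ks_up, decreasing = TRUE), 0, ks_dn)
  segment <- ifelse(offsets > 0, "oro", "hypo")
  proj <- drop(lumen$vertices %*% n) - e0
  ref_plane <- planes$e_plane
  b <- plane_basis(ref_plane)
  areas <- numeric(length(offsets))
  for (i in seq_along(offsets)) {
    d <- proj - offsets[i]
    d[abs(d) < 1e-12] <- 1e-12
    cut <- plane_cut(lumen, d)
    if (is.null(cut)) {
      areas[i] <- 0
      warning(sprintf("empty airway section at offset %+.1f mm (collapsed lumen?)",
                      offsets[i]))
      next
    }
    pl_i <- plane3d(ref_plane$point + offsets[i] * n, n)
    loops <- lapply(chain_loops(cut$segs, cut$points),
                    function(j) cut$points[j, , drop = FALSE])
    loops2d <- lapply(loops, function(L)
      project2d(snap_to_plane(L, pl_i), pl_i, b))
    la <- vapply(loops2d, function(p) abs(shoelace_area(p)), numeric(1))
    areas[i] <- if (area_mode == "largest") max(la) else
      sum(loop_signs(loops2d) * la)
  }
  oro_idx <- which(segment == "oro" | offsets == 0)   # E-plane also considered
  hyp_idx <- which(segment == "hypo")
  io <- oro_idx[which.min(areas[oro_idx])]
  ih <- hyp_idx[which.min(areas[hyp_idx])]
  out <- list(profile = data.frame(segment = segment, offset_mm = offsets,
                                   area_mm2 = areas),
              spacing = spacing, area_mode = area_mode,
              min_csa_oro = areas[io], min_offset_oro = offsets[io],
              min_csa_hypo = areas[ih], min_offset_hypo = offsets[ih])
  class(out) <- "airway_profile"
  out
}

#' @export
print.airway_profile <- function(x, ...) {
  cat(sprintf("<airway_profile> %d offsets at %.2g mm spacing\n",
              nrow(x$profile), x$spacing))
  cat(sprintf("  minCSA oro  %.2f mm^2 at %+.1f mm\n", x$min_csa_oro, x$min_offset_oro))
  cat(sprintf("  minCSA hypo %.2f mm^2 at %+.1f mm\n", x$min_csa_hypo, x$min_offset_hypo))
  invisible(x)
}

#' Percentage change of airway quantities
#'
#' All percentages are `100 * post / pre`; 100 means no change.
#'
#' @param pre_volumes,post_volumes [airway_volumes()] at the two timepoints.
#' @param pre_profile,post_profile optional [csa_profile()] results; when
#'   given, minCSA percentages are included.
#' @return Object of class `airway_change`: `volume_pct` (named: naso, oro,
#'   hypo, total) and `min_csa_pct` (named: oro, hypo; `NULL` without
#'   profiles).
#' @export
airway_change <- function(pre_volumes, post_volumes,
                          pre_profile = NULL, post_profile = NULL) {
  pick <- function(v) c(naso = v$naso, oro = v$oro, hypo = v$hypo, total = v$total)
  pre <- pick(pre_volumes); post <- pick(post_volumes)
  if (any(pre <= 0))
    stop("undefined percentage: zero pre-operative volume in ",
         paste(names(pre)[pre <= 0], collapse = ", "))
  out <- list(volume_pct = 100 * post / pre, min_csa_pct = NULL)
  if (!is.null(pre_profile) && !is.null(post_profile)) {
    mpre <- c(oro = pre_profile$min_csa_oro, hypo = pre_profile$min_csa_hypo)
    mpost <- c(oro = post_profile$min_csa_oro, hypo = post_profile$min_csa_hypo)
    if (any(mpre <= 0))
      stop("undefined percentage: zero pre-operative minCSA in ",
           paste(names(mpre)[mpre <= 0], collapse = ", "))
    out$min_csa_pct <- 100 * mpost / mpre
  }
  class(out) <- "airway_change"
  out
}

#' @export
print.airway_change <- function(x, ...) {
  cat("<airway_change> volume %:",
      paste(sprintf("%s %.1f", names(x$volume_pct), x$volume_pct), collapse = ", "), "\n")
  if (!is.null(x$min_csa_pct))
    cat("  minCSA %:",
        paste(sprintf("%s %.1f", names(x$min_csa_pct), x$min_csa_pct), collapse = ", "), "\n")
  invisible(x)
}
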