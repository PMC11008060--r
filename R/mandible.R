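# Condylar and symphyseal positional change in the cranial frame: per-condyle
# rigid pose change decomposed into axis/plane deviations and Euler-angle
# rotations, and the symphysis centre-point shift in the midsagittal plane.

#' Crop a mesh to a region of interest
#'
#' Keeps the faces whose centroids fall inside the specification.
#'
#' @param mesh a [surface_mesh()].
#' @param region_spec list with `type = "box"` (`min`, `max`),
#'   `"sphere"` (`center`, `radius`) or `"halfspace"` (`point`, `normal`),
#'   in the mesh's current coordinates.
#' @return A `surface_mesh` (generally not watertight).
#' @export
crop_region <- function(mesh, region_spec) {
  keep <- region_select(face_centroids(mesh), region_spec)
  if (!any(keep)) stop("empty crop: region contains no face centroids")
  f <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices)); remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE], matrix(remap[f], ncol = 3),
               name = mesh$name, drop_degenerate = FALSE)
}

#' Best-fit rigid transform between two poses of the same region
#'
#' After skull superimposition, the pose change of a condyle (assumed rigid:
#' unchanged in shape by the surgery) is the rigid transform mapping its
#' pre-operative region mesh onto the post-operative one, recovered by ICP.
#'
#' @param region_pre,region_post [surface_mesh()] crops of the same
#'   anatomical structure at the two timepoints, in the common cranial frame.
#' @param shape_change_rms warn when the final RMS exceeds this (mm): the
#'   rigid-shape assumption is then questionable (remodelled/resected
#'   condyle).
#' @param ... passed to [register_icp()].
#' @return A [rigid_transform()] mapping pre onto post (attribute `rms`).
#' @details Plain centroid-initialized ICP can lock into a tangential-slide
#'   local minimum for pose changes of tens of degrees. The fit therefore
#'   starts from the principal-axes (inertia) alignment of the two vertex
#'   sets in all four proper sign combinations, plus the centroid init, and
#'   keeps the solution with the lowest RMS — deterministic, no RNG.
#' @export
fit_region_transform <- function(region_pre, region_post,
                                 shape_change_rms = 0.5, ...) {
  inits <- c(list(NULL), pca_inits(region_pre$vertices, region_post$vertices))
  best <- NULL
  for (init in inits) {
    fit <- tryCatch(register_icp(region_pre, region_post, init = init, ...),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$rms < best$rms)) best <- fit
  }
  if (is.null(best)) stop("region fit failed from every initialization")
  if (best$rms > shape_change_rms)
    warning(sprintf(paste0("region fit RMS %.3f mm exceeds %.2f mm: rigid-",
                           "shape assumption may be violated"),
                    best$rms, shape_change_rms))
  structure(best$transform, rms = best$rms)
}

# principal-axes initializations: eigenvectors of the vertex covariances
# aligned in the four proper sign combinations (covers the 180-degree flip
# ambiguity of inertia alignment)
pca_inits <- function(p, q) {
  ep <- eigen(stats::cov(p), symmetric = TRUE)$vectors
  eq <- eigen(stats::cov(q), symmetric = TRUE)$vectors
  if (det(ep) < 0) ep[, 3] <- -ep[, 3]
  if (det(eq) < 0) eq[, 3] <- -eq[, 3]
  cp <- colMeans(p); cq <- colMeans(q)
  lapply(list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
         function(s) {
           R <- eq %*% diag(s) %*% t(ep)
           rigid_transform(R, cq - drop(R %*% cp))
         })
}

#' Condylar displacement metrics from a pose-change transform
#'
#' Resolves the displacement of the condylar reference point under the pose
#' change onto the frame axes (signed dX anterior, dY left-lateral, dZ
#' cranial), the in-plane deviation magnitudes (dXY, dXZ, dYZ), the Euclidean
#' deviation dXYZ, and the rotations about the frame axes as intrinsic X-Y-Z
#' Euler angles (phi_x, theta_y, psi_z) in degrees.
#'
#' @param transform a [rigid_transform()] expressed in the cranial frame
#'   (from [fit_region_transform()]).
#' @param reference_point the condyle-region reference (pre-operative crop
#'   centroid), length-3, frame coordinates.
#' @param side `"left"` or `"right"`.
#' @return Object of class `condyle_displacement`: list with fields `dX`,
#'   `dY`, `dZ` (signed mm), `dXY`, `dXZ`, `dYZ`, `dXYZ` (non-negative mm),
#'   `phi_x`, `theta_y`, `psi_z` (degrees, each in (-180, 180]),
#'   `gimbal_lock` flag and `side`.
#' @export
condyle_displacement <- function(transform, reference_point,
                                 side = c("left", "right")) {
  side <- match.arg(side)
  p <- as.numeric(reference_point)
  d <- transform_apply(transform, p) - p
  ang <- euler_angles(transform$rotation)
  out <- list(
    dX = d[1], dY = d[2], dZ = d[3],
    dXY = sqrt(d[1]^2 + d[2]^2),
    dXZ = sqrt(d[1]^2 + d[3]^2),
    dYZ = sqrt(d[2]^2 + d[3]^2),
    dXYZ = sqrt(sum(d^2)),
    phi_x = unname(ang["phi_x"]), theta_y = unname(ang["theta_y"]),
    psi_z = unname(ang["psi_z"]),
    gimbal_lock = isTRUE(attr(ang, "gimbal_lock")),
    side = side)
  class(out) <- "condyle_displacement"
  out
}

#' @export
print.condyle_displacement <- function(x, ...) {
  cat(sprintf("<condyle_displacement> side %s\n", x$side))
  cat(sprintf("  dX %.3f  dY %.3f  dZ %.3f  (mm, signed)\n", x$dX, x$dY, x$dZ))
  cat(sprintf("  dXY %.3f  dXZ %.3f  dYZ %.3f  dXYZ %.3f  (mm)\n",
              x$dXY, x$dXZ, x$dYZ, x$dXYZ))
  cat(sprintf("  phi_x %.3f  theta_y %.3f  psi_z %.3f  (deg)%s\n",
              x$phi_x, x$theta_y, x$psi_z,
              if (x$gimbal_lock) "  [gimbal lock]" else ""))
  invisible(x)
}

#' Symphysis centre-point deviation in the midsagittal plane
#'
#' The symphysis (or fibular neo-symphysis) may differ in shape between
#' timepoints, so its position is compared through the centre point of its
#' intersection with the midsagittal plane: each mesh is sectioned, the area
#' centroid taken, and the post-minus-pre centroid difference resolved on the
#' frame X (anterior positive) and Z (cranial positive) axes. A posterior
#' (setback-like) shift therefore yields a negative `s_dx`.
#'
#' @param pre_mesh,post_mesh symphyseal region meshes at the two timepoints,
#'   both intersecting the midsagittal plane.
#' @param plane the midsagittal [plane3d()] (see [midsagittal_plane()]).
#' @param axis_x,axis_z frame axes; defaults assume meshes already in frame
#'   coordinates.
#' @return Object of class `symphysis_deviation`: `s_dx`, `s_dz` (signed mm),
#'   `s_dxz` (non-negative mm), `centre_pre`, `centre_post`.
#' @export
symphysis_deviation <- function(pre_mesh, post_mesh, plane,
                                axis_x = c(1, 0, 0), axis_z = c(0, 0, 1)) {
  c_pre <- tryCatch(contour_centroid(section_with_plane(pre_mesh, plane)),
                    error = function(e)
                      stop("symphysis not restored at midline (pre): ",
                           conditionMessage(e)))
  c_post <- tryCatch(contour_centroid(section_with_plane(post_mesh, plane)),
                     error = function(e)
                       stop("symphysis not restored at midline (post): ",
                            conditionMessage(e)))
  d <- c_post - c_pre
  out <- list(s_dx = sum(d * axis_x), s_dz = sum(d * axis_z),
              s_dxz = sqrt(sum(d * axis_x)^2 + sum(d * axis_z)^2),
              centre_pre = c_pre, centre_post = c_post)
  class(out) <- "symphysis_deviation"
  out
}

#' @export
print.symphysis_deviation <- function(x, ...) {
  cat(sprintf("<symphysis_deviation> S_dX %.3f  S_dZ %.3f  S_dXZ %.3f (mm)\n",
              x$s_dx, x$s_dz, x$s_dxz))
  invisible(x)
}
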