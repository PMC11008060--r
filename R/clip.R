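# Half-space clipping with capping. Cut triangles are split along the plane;
# the boundary polygon(s) are capped by a fan so the result stays watertight
# and mesh_volume remains valid. Fan capping is exact for star-shaped cut
# loops (all airway and phantom sections are convex).

#' Clip a mesh to the slab between two planes
#'
#' Keeps the part of the mesh on the positive side of both planes (normals
#' point into the kept slab) and caps the cut faces with the section
#' contours, so [mesh_volume()] is valid on the result.
#'
#' @param mesh a watertight [surface_mesh()].
#' @param lower,upper [plane3d()] objects with normals pointing into the
#'   kept slab.
#' @return A watertight `surface_mesh`.
#' @export
clip_between_planes <- function(mesh, lower, upper) {
  dl <- plane_distance(lower, mesh$vertices)
  du <- plane_distance(upper, mesh$vertices)
  if (!any(dl > -1e-12 & du > -1e-12))
    stop("empty geometry: kept slab contains no part of the mesh")
  out <- clip_halfspace(mesh, lower)
  clip_halfspace(out, upper)
}

#' Clip a mesh by a single plane
#'
#' Keeps the side the normal points to and caps the cut.
#'
#' @param mesh a watertight [surface_mesh()].
#' @param plane a [plane3d()].
#' @param cap triangulate the cut boundary (keep `TRUE` whenever volumes are
#'   needed downstream).
#' @return A `surface_mesh`.
#' @export
clip_halfspace <- function(mesh, plane, cap = TRUE) {
  d <- plane_distance(plane, mesh$vertices)
  d[abs(d) < 1e-12] <- 1e-12
  f <- mesh$faces
  pos <- matrix(d[f] > 0, ncol = 3)
  np <- rowSums(pos)
  if (all(np == 3L)) return(mesh)               # plane outside extent
  if (all(np == 0L)) stop("empty geometry: mesh entirely clipped away")

  cut <- plane_cut(mesh, d)
  nv0 <- nrow(mesh$vertices)
  if (is.null(cut)) {  # plane separates components without cutting faces
    pts <- matrix(numeric(0), 0, 3)
    segs <- matrix(integer(0), 0, 2)
  } else {
    pts <- snap_to_plane(cut$points, plane)
    segs <- cut$segs + nv0
  }
  verts <- rbind(mesh$vertices, pts)            # crossing points appended
  mixed_idx <- which(np == 1L | np == 2L)
  # plane_cut visits mixed faces in file order; row r of cut$segs belongs to
  # mixed_idx[r] and its two point ids are the face's crossing points

  keep_faces <- f[np == 3L, , drop = FALSE]
  new_faces <- matrix(integer(0), 0, 3)
  if (length(mixed_idx)) {
    fm <- f[mixed_idx, , drop = FALSE]
    pm <- pos[mixed_idx, , drop = FALSE]
    npm <- np[mixed_idx]
    # rotate each face so the lone inside (np==1) or lone outside (np==2)
    # vertex comes first, preserving winding
    lone <- integer(length(mixed_idx))
    lone[npm == 1L] <- max.col(pm[npm == 1L, , drop = FALSE], "first")
    lone[npm == 2L] <- max.col(!pm[npm == 2L, , drop = FALSE], "first")
    rot <- cbind(lone, lone %% 3L + 1L, (lone + 1L) %% 3L + 1L)
    fr <- matrix(fm[cbind(rep(seq_len(nrow(fm)), 3L), as.vector(rot))], ncol = 3)
    # crossing points per face: p_a on the edge leaving the lone vertex
    # (v1-v2), p_b on the edge entering it (v3-v1); identify by edge key
    nvk <- as.numeric(nv0) + 1
    key_a <- pmin(fr[, 1], fr[, 2]) * nvk + pmax(fr[, 1], fr[, 2])
    k1 <- cut$point_keys[cut$segs[, 1]]
    swap <- k1 != key_a
    pa <- ifelse(swap, segs[, 2], segs[, 1])
    pb <- ifelse(swap, segs[, 1], segs[, 2])
    one <- npm == 1L
    if (any(one))  # keep triangle (v1, p_a, p_b)
      new_faces <- rbind(new_faces,
                         cbind(fr[one, 1], pa[one], pb[one]))
    two <- npm == 2L
    if (any(two))  # drop v1; keep quad (p_a, v2, v3, p_b)
      new_faces <- rbind(new_faces,
                         cbind(pa[two], fr[two, 2], fr[two, 3]),
                         cbind(pa[two], fr[two, 3], pb[two]))
  }
  faces_out <- rbind(keep_faces, new_faces)

  if (cap && nrow(segs)) {
    loops <- chain_loops(cut$segs, pts)
    b <- plane_basis(plane)
    for (ids in loops) {
      L <- pts[ids, , drop = FALSE]
      # cap normal must point out of the kept (positive) side, i.e. -normal:
      # traverse clockwise about the normal (u x v = normal convention)
      if (shoelace_area(project2d(L, plane, b)) > 0) {
        ids <- rev(ids); L <- L[rev(seq_len(nrow(L))), , drop = FALSE]
      }
      apex <- colMeans(L)
      ai <- nrow(verts) + 1L
      verts <- rbind(verts, apex)
      k <- length(ids)
      li <- nv0 + ids
      faces_out <- rbind(faces_out,
                         cbind(ai, li, li[c(2:k, 1)]))
    }
  }
  # drop unreferenced vertices
  used <- sort(unique(as.vector(faces_out)))
  remap <- integer(nrow(verts)); remap[used] <- seq_along(used)
  out <- surface_mesh(verts[used, , drop = FALSE],
                      matrix(remap[faces_out], ncol = 3),
                      name = mesh$name, drop_degenerate = FALSE)
  wt <- watertight_report(mesh)
  if (cap && wt$watertight) {
    wo <- watertight_report(out)
    if (!wo$watertight)
      stop("geometry error: capping failed (", wo$boundary_edges,
           " boundary edges after clip)")
  }
  out
}
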