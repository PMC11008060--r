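# Triangulated surface meshes in mm. Vertices are an n x 3 double matrix,
# faces an m x 3 integer matrix of vertex indices. STL stores float32; all
# internal computation is double precision.

#' Construct a surface mesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates in mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param name free-text label.
#' @param drop_degenerate drop faces with area < 1e-12 mm^2 (segmentation
#'   exports commonly contain slivers).
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, name = "", drop_degenerate = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (!all(is.finite(vertices))) stop("mesh has non-finite vertex coordinates")
  if (nrow(faces) == 0L || nrow(vertices) == 0L)
    stop("empty geometry: mesh has no ", if (nrow(faces) == 0L) "faces" else "vertices")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range [1, ", nrow(vertices), "]")
  m <- structure(list(vertices = vertices, faces = faces, name = name),
                 class = "surface_mesh")
  if (drop_degenerate) {
    a <- face_areas(m)
    bad <- a < 1e-12
    if (any(bad)) {
      m$faces <- m$faces[!bad, , drop = FALSE]
      if (nrow(m$faces) == 0L) stop("empty geometry: all faces degenerate")
      attr(m, "dropped_degenerate") <- sum(bad)
    }
  }
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  wt <- watertight_report(x)
  cat(sprintf("<surface_mesh '%s'> %d vertices, %d faces, %s\n",
              x$name, nrow(x$vertices), nrow(x$faces),
              if (wt$watertight) "watertight" else
                sprintf("%d boundary edges", wt$boundary_edges)))
  invisible(x)
}

# per-face double areas and areas
face_cross <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

face_areas <- function(mesh) {
  cr <- face_cross(mesh)
  0.5 * sqrt(rowSums(cr^2))
}

face_normals <- function(mesh) {
  cr <- face_cross(mesh)
  n <- sqrt(rowSums(cr^2))
  n[n < 1e-300] <- 1
  cr / n
}

face_centroids <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' Watertightness report
#'
#' A mesh is watertight and consistently oriented when every undirected edge
#' is shared by exactly two faces with opposite winding.
#'
#' @param mesh a [surface_mesh()].
#' @return List with `watertight` (logical), `boundary_edges` (count of edges
#'   used by exactly one face) and `consistent` (orientation consistency).
#' @export
watertight_report <- function(mesh) {
  f <- mesh$faces
  a <- c(f[, 1], f[, 2], f[, 3])
  b <- c(f[, 2], f[, 3], f[, 1])
  nv <- as.numeric(nrow(mesh$vertices)) + 1
  dir_key <- a * nv + b
  und_key <- pmin(a, b) * nv + pmax(a, b)
  und_tab <- table_counts(und_key)
  boundary <- sum(und_tab == 1L)
  watertight <- all(und_tab == 2L)
  consistent <- watertight && !anyDuplicated(dir_key)
  list(watertight = watertight, boundary_edges = boundary,
       consistent = consistent)
}

# counts of each distinct value (fast table for numeric keys)
table_counts <- function(key) {
  u <- unique(key)
  tabulate(match(key, u), nbins = length(u))
}

#' Enclosed volume of a watertight mesh
#'
#' Signed-tetrahedron summation over faces: positive for consistent outward
#' orientation, invariant under rigid motion.
#'
#' @param mesh a watertight, consistently oriented [surface_mesh()].
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  wt <- watertight_report(mesh)
  if (!wt$watertight)
    stop("mesh is not watertight: ", wt$boundary_edges,
         " boundary edges; volume undefined")
  if (!wt$consistent)
    stop("mesh orientation inconsistent; volume undefined")
  v <- mesh$vertices; f <- mesh$faces
  v1 <- v[f[, 1], , drop = FALSE]
  cr <- face_cross(mesh)  # (v2-v1) x (v3-v1)
  # v1 . ((v2 - v1) x (v3 - v1)) = v1 . (v2 x v3) since v1.(v1 x .) = 0
  sum(rowSums(v1 * cr)) / 6
}

#' Segmentation volume quality control
#'
#' Compares volumes of anatomically stable reference regions of the pre- and
#' post-operative meshes; a relative difference above `tolerance` indicates a
#' segmentation inconsistency and the patient should be excluded.
#'
#' @param pre,post watertight [surface_mesh()] objects.
#' @param tolerance maximum allowed relative volume difference
#'   `|post - pre| / pre` (default 0.02).
#' @param region optional bounding specification (see [crop_region()])
#'   selecting the stable region compared; default compares whole meshes.
#' @return List with `pass`, `volume_pre`, `volume_post`, `ratio`
#'   (post/pre) and `relative_difference`.
#' @export
volume_qc <- function(pre, post, tolerance = 0.02, region = NULL) {
  if (!is.null(region)) {
    pre <- crop_region(pre, region)
    post <- crop_region(post, region)
  }
  vp <- mesh_volume(pre)
  vq <- mesh_volume(post)
  rel <- abs(vq - vp) / abs(vp)
  list(pass = rel <= tolerance, volume_pre = vp, volume_post = vq,
       ratio = vq / vp, relative_difference = rel, tolerance = tolerance)
}

#' Merge coincident vertices
#'
#' Vertices within `tol` of each other (on a snapped grid) are merged;
#' faces collapsing to fewer than three distinct vertices and exact
#' duplicate faces are dropped.
#'
#' @param mesh a [surface_mesh()].
#' @param tol merge tolerance in mm.
#' @return A `surface_mesh` with attributes `merged_vertices` and
#'   `dropped_faces` recording the cleanup counts.
#' @export
merge_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  n_merged <- nrow(v) - sum(first)
  f <- matrix(map[mesh$faces], ncol = 3)
  collapsed <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  # duplicate faces (same vertex set, either winding) kept once
  fs <- cbind(pmin(f[, 1], f[, 2], f[, 3]),
              pmax(f[, 1], f[, 2], f[, 3]))
  fmid <- f[, 1] + f[, 2] + f[, 3] - fs[, 1] - fs[, 2]
  dup <- duplicated(paste(fs[, 1], fmid, fs[, 2]))
  keep <- !collapsed & !dup
  if (!any(keep)) stop("empty geometry after vertex merge")
  out <- surface_mesh(v[first, , drop = FALSE], f[keep, , drop = FALSE],
                      name = mesh$name)
  attr(out, "merged_vertices") <- n_merged
  attr(out, "dropped_faces") <- sum(!keep) + (attr(out, "dropped_degenerate") %||% 0L)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a plane
#'
#' @param point a 3D point on the plane, mm.
#' @param normal plane normal (normalized internally; must be non-zero).
#' @return Object of class `plane3d` with unit `normal`.
#' @export
plane3d <- function(point, normal) {
  point <- as.numeric(point); normal <- as.numeric(normal)
  stopifnot(length(point) == 3L, length(normal) == 3L)
  structure(list(point = point, normal = unit3(normal)), class = "plane3d")
}

#' @export
print.plane3d <- function(x, ...) {
  cat(sprintf("<plane3d> point (%.3f, %.3f, %.3f), normal (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Signed distance of points from a plane
#'
#' Positive on the side the normal points to.
#'
#' @param plane a [plane3d()].
#' @param points n x 3 matrix or length-3 point.
#' @return Numeric vector of signed distances in mm.
#' @export
plane_distance <- function(plane, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  drop(sweep(points, 2, plane$point) %*% plane$normal)
}

# deterministic orthonormal in-plane basis (u, v) with u x v = normal
plane_basis <- function(plane) {
  n <- plane$normal
  e <- diag(3)[, which.min(abs(n))]
  u <- unit3(e - sum(e * n) * n)
  v <- cross3(n, u)
  list(u = u, v = v)
}
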