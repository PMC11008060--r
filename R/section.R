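# Mesh-plane intersection. Crossing points are keyed by the mesh edge that
# generated them, so chaining across adjacent faces is exact (no coordinate
# tolerance is needed beyond the 1e-6 mm vertex weld at load time).

#' Intersect a mesh with a plane
#'
#' Returns all closed intersection loops, each built by chaining
#' triangle-plane segment crossings across shared mesh edges, ordered by
#' descending enclosed area.
#'
#' @param mesh a [surface_mesh()]. Non-watertight meshes are permitted for
#'   sectioning provided the cut itself closes.
#' @param plane a [plane3d()].
#' @return Object of class `section_contour`: list with `loops` (list of
#'   k x 3 point matrices, implicitly closed: last point connects to first)
#'   and `plane`.
#' @export
section_with_plane <- function(mesh, plane) {
  d <- plane_distance(plane, mesh$vertices)
  d[abs(d) < 1e-12] <- 1e-12  # on-plane vertices treated as positive side
  cut <- plane_cut(mesh, d)
  if (is.null(cut))
    stop("empty contour: plane does not intersect the mesh")
  loops <- lapply(chain_loops(cut$segs, cut$points),
                  function(i) cut$points[i, , drop = FALSE])
  loops <- lapply(loops, snap_to_plane, plane = plane)
  b <- plane_basis(plane)
  areas <- vapply(loops, function(L) abs(shoelace_area(project2d(L, plane, b))),
                  numeric(1))
  structure(list(loops = loops[order(-areas)], plane = plane),
            class = "section_contour")
}

#' @export
print.section_contour <- function(x, ...) {
  cat(sprintf("<section_contour> %d loop(s), %s points\n", length(x$loops),
              paste(vapply(x$loops, nrow, integer(1)), collapse = "/")))
  invisible(x)
}

# project loop points exactly onto the plane (removes 1e-16 float residue)
snap_to_plane <- function(L, plane) {
  d <- plane_distance(plane, L)
  L - outer(d, plane$normal)
}

# crossing segments of a mesh against a plane given perturbed signed
# distances d (no zeros). Returns unique crossing points (keyed by mesh
# edge) and an m x 2 matrix of point ids, one row per crossing face.
# faces_sub optionally restricts to a subset of face indices.
plane_cut <- function(mesh, d, faces_sub = NULL) {
  f <- if (is.null(faces_sub)) mesh$faces else mesh$faces[faces_sub, , drop = FALSE]
  pos <- matrix(d[f] > 0, ncol = 3)
  np <- rowSums(pos)
  mixed <- np == 1L | np == 2L
  if (!any(mixed)) return(NULL)
  fm <- f[mixed, , drop = FALSE]
  # edges of each face: (1,2), (2,3), (3,1); crossing where signs differ
  ea <- cbind(fm[, 1], fm[, 2], fm[, 3])
  eb <- cbind(fm[, 2], fm[, 3], fm[, 1])
  crossing <- matrix(d[ea] * d[eb] < 0, ncol = 3)
  stopifnot(all(rowSums(crossing) == 2L))
  a <- t(ea)[t(crossing)]            # first endpoints, 2 per face in order
  b <- t(eb)[t(crossing)]
  nv <- as.numeric(nrow(mesh$vertices)) + 1
  key <- pmin(a, b) * nv + pmax(a, b)
  u <- !duplicated(key)
  uid <- match(key, key[u])
  ua <- a[u]; ub <- b[u]
  da <- d[ua]; db <- d[ub]
  tt <- da / (da - db)
  pts <- mesh$vertices[ua, , drop = FALSE] +
    tt * (mesh$vertices[ub, , drop = FALSE] - mesh$vertices[ua, , drop = FALSE])
  segs <- matrix(uid, ncol = 2, byrow = TRUE)
  list(points = pts, segs = segs, point_keys = key[u])
}

# chain crossing segments into closed loops of node indices. Every node
# (crossing point) must be used by exactly two segments; otherwise the cut
# is open. `points` is used only for error reporting.
chain_loops <- function(segs, points) {
  m <- nrow(segs)
  slots <- c(segs[, 1], segs[, 2])   # slot s: segment ((s-1) %% m) + 1
  o <- order(slots)
  ns <- slots[o]
  cnt <- table_counts(slots)
  if (any(cnt != 2L)) {
    bad <- unique(slots)[cnt != 2L]
    ep <- points[bad[seq_len(min(4, length(bad)))], , drop = FALSE]
    stop("open section chains (non-watertight cut): ", length(bad),
         " unmatched endpoint(s), first near (",
         paste(sprintf("%.3f", ep[1, ]), collapse = ", "), ")")
  }
  mate <- integer(2 * m)
  i1 <- o[seq(1, 2 * m, 2)]; i2 <- o[seq(2, 2 * m, 2)]
  mate[i1] <- i2; mate[i2] <- i1
  visited <- logical(m)
  loops <- list()
  for (s0 in seq_len(m)) {
    if (visited[s0]) next
    node_seq <- integer(0)
    seg <- s0; end_in <- 1L
    repeat {
      visited[seg] <- TRUE
      node_seq <- c(node_seq, segs[seg, end_in])
      exit_slot <- (2L - end_in) * m + seg     # the other end's slot
      nxt <- mate[exit_slot]
      seg2 <- ((nxt - 1L) %% m) + 1L
      end2 <- ((nxt - 1L) %/% m) + 1L
      if (seg2 == s0) break
      seg <- seg2; end_in <- end2
    }
    if (length(node_seq) >= 3L)
      loops[[length(loops) + 1L]] <- node_seq
  }
  if (length(loops) == 0L)
    stop("empty contour: section produced no closed loop of 3+ points")
  loops
}

project2d <- function(L, plane, basis = plane_basis(plane)) {
  q <- sweep(L, 2, plane$point)
  cbind(drop(q %*% basis$u), drop(q %*% basis$v))
}

shoelace_area <- function(p2) {
  x <- p2[, 1]; y <- p2[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

shoelace_centroid <- function(p2) {
  x <- p2[, 1]; y <- p2[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(list(area = a, centroid = c(NA_real_, NA_real_)))
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  list(area = a, centroid = c(cx, cy))
}

# even-odd crossing-number point-in-polygon (boundary points undefined;
# callers use loop vertices of *other* loops, distinct by construction)
point_in_polygon <- function(pt, p2) {
  x <- p2[, 1]; y <- p2[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  crosses <- ((y > pt[2]) != (yn > pt[2]))
  if (!any(crosses)) return(FALSE)
  xi <- x[crosses] + (pt[2] - y[crosses]) / (yn[crosses] - y[crosses]) *
    (xn[crosses] - x[crosses])
  sum(xi > pt[1]) %% 2L == 1L
}

# even-odd sign per loop: (-1)^(number of other loops containing it)
loop_signs <- function(loops2d) {
  k <- length(loops2d)
  if (k == 1L) return(1)
  depth <- integer(k)
  for (i in seq_len(k)) {
    pt <- loops2d[[i]][1, ]
    for (j in seq_len(k)[-i])
      if (point_in_polygon(pt, loops2d[[j]])) depth[i] <- depth[i] + 1L
  }
  (-1)^depth
}

#' Area enclosed by a section contour
#'
#' Planar polygon area by the shoelace formula in plane coordinates. In
#' `"sum"` mode nested loops alternate sign (even-odd winding), so holes
#' subtract; `"largest"` returns the single loop of maximal area.
#'
#' @param contour a `section_contour` from [section_with_plane()].
#' @param mode `"sum"` or `"largest"`.
#' @param check_simple verify loops are non-self-intersecting (O(k^2) per
#'   loop; off by default — loops chained from a watertight cut are simple
#'   by construction).
#' @return Area in mm^2.
#' @export
contour_area <- function(contour, mode = c("sum", "largest"),
                         check_simple = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(contour, "section_contour"), length(contour$loops) >= 1L)
  b <- plane_basis(contour$plane)
  loops2d <- lapply(contour$loops, project2d, plane = contour$plane, basis = b)
  if (check_simple)
    for (i in seq_along(loops2d))
      if (!is_simple_polygon(loops2d[[i]]))
        stop("geometry error: self-intersecting contour loop (loop ", i, ")")
  areas <- vapply(loops2d, function(p) abs(shoelace_area(p)), numeric(1))
  if (mode == "largest") return(max(areas))
  sum(loop_signs(loops2d) * areas)
}

#' Area centroid of a section contour
#'
#' Area-weighted centroid of the enclosed planar region (holes subtract via
#' even-odd winding), mapped back to 3D; lies on the contour's plane. This is
#' the region centroid, not the vertex mean, so it is robust to non-uniform
#' tessellation.
#'
#' @param contour a `section_contour`.
#' @return Length-3 point in mm.
#' @export
contour_centroid <- function(contour) {
  stopifnot(inherits(contour, "section_contour"), length(contour$loops) >= 1L)
  b <- plane_basis(contour$plane)
  loops2d <- lapply(contour$loops, project2d, plane = contour$plane, basis = b)
  sg <- loop_signs(loops2d)
  acc_a <- 0; acc_c <- c(0, 0)
  for (i in seq_along(loops2d)) {
    sc <- shoelace_centroid(loops2d[[i]])
    if (!is.finite(sc$centroid[1])) next
    w <- sg[i] * abs(sc$area)
    acc_a <- acc_a + w
    acc_c <- acc_c + w * sc$centroid
  }
  if (abs(acc_a) < 1e-12) stop("geometry error: contour has zero enclosed area")
  c2 <- acc_c / acc_a
  contour$plane$point + c2[1] * b$u + c2[2] * b$v
}

# segment-intersection test for polygon simplicity (non-adjacent edges only)
is_simple_polygon <- function(p2) {
  n <- nrow(p2)
  if (n < 4L) return(TRUE)
  a <- p2; bb <- p2[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]  # edge n is adjacent to edge 1
    if (!length(js)) next
    if (any(segments_intersect(a[i, ], bb[i, ], a[js, , drop = FALSE],
                               bb[js, , drop = FALSE]))) return(FALSE)
  }
  TRUE
}

segments_intersect <- function(p, q, r, s) {
  # proper intersection of segment (p,q) with segments (r_i, s_i), 2D
  d1 <- (q[1] - p[1]) * (r[, 2] - p[2]) - (q[2] - p[2]) * (r[, 1] - p[1])
  d2 <- (q[1] - p[1]) * (s[, 2] - p[2]) - (q[2] - p[2]) * (s[, 1] - p[1])
  d3 <- (s[, 1] - r[, 1]) * (p[2] - r[, 2]) - (s[, 2] - r[, 2]) * (p[1] - r[, 1])
  d4 <- (s[, 1] - r[, 1]) * (q[2] - r[, 2]) - (s[, 2] - r[, 2]) * (q[1] - r[, 1])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Export a section contour as JSON
#'
#' Debug/visualization export: the plane (point + normal) and each loop as a
#' list of 3D points.
#'
#' @param contour a `section_contour`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
contour_to_json <- function(contour, path) {
  obj <- list(plane = list(point = contour$plane$point,
                           normal = contour$plane$normal),
              loops = lapply(contour$loops, function(L)
                unname(apply(L, 1, function(r) r, simplify = FALSE))))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
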