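# Superimposition of pre/post meshes on surgically unchanged anatomy and
# construction of the skull-aligned coordinate frame (X anterior, Y
# left-lateral, Z cranial) in which all deviations are expressed.

#' Rigid iterative-closest-point registration
#'
#' Point-to-point ICP: vertex correspondences by nearest neighbour, pose
#' update by the Kabsch (SVD) solution. Correspondences are sampled by a
#' deterministic evenly-spaced stride, so the result is fully reproducible
#' without touching the RNG. The mask restricts registration to the
#' surgically unchanged region (the cranium), which must be excluded from
#' alignment error introduced by the reconstruction itself.
#'
#' @param moving,fixed [surface_mesh()] objects; the returned transform maps
#'   `moving` onto `fixed`.
#' @param mask_region optional region specification (see [crop_region()]) or
#'   a `surface_mesh` whose bounding box (plus 1 mm margin) is used; applied
#'   to the moving vertices after initialization. `NULL` uses all vertices.
#' @param init optional initial [rigid_transform()]; default pre-aligns
#'   centroids (of the masked region when a mask is given).
#' @param max_iter,tol convergence: relative RMS change < `tol` (default
#'   1e-8) or `max_iter` (default 200) iterations.
#' @param max_points at most this many moving vertices are used (evenly
#'   strided).
#' @return List with `transform` (a `rigid_transform`), `rms` (final
#'   point-to-point RMS in mm), `iterations`, and `trace` (RMS per
#'   iteration).
#' @export
register_icp <- function(moving, fixed, mask_region = NULL, init = NULL,
                         max_iter = 200L, tol = 1e-8, max_points = 2000L) {
  mv <- moving$vertices
  fv <- fixed$vertices
  if (!is.null(mask_region)) {
    if (inherits(mask_region, "surface_mesh")) {
      rg <- apply(mask_region$vertices, 2, range)
      mask_region <- list(type = "box", min = rg[1, ] - 1, max = rg[2, ] + 1)
    }
    sel <- region_select(if (is.null(init)) mv else transform_apply(init, mv),
                         mask_region)
    if (sum(sel) < 100L)
      stop("insufficient masked points for registration: ", sum(sel), " < 100")
    mv <- mv[sel, , drop = FALSE]
  }
  if (nrow(mv) > max_points)
    mv <- mv[round(seq(1L, nrow(mv), length.out = max_points)), , drop = FALSE]
  if (is.null(init))
    init <- rigid_transform(diag(3), colMeans(fv) - colMeans(mv))
  Tcur <- init
  trace <- numeric(0)
  bad_run <- 0L
  for (it in seq_len(max_iter)) {
    p <- transform_apply(Tcur, mv)
    nn <- nearest_vertex(p, fv)
    q <- fv[nn$index, , drop = FALSE]
    rms <- sqrt(mean(nn$dist2))
    trace <- c(trace, rms)
    if (it > 1L) {
      prev <- trace[it - 1L]
      if (rms > prev * (1 + 1e-12)) bad_run <- bad_run + 1L else bad_run <- 0L
      if (bad_run >= 10L)
        stop("ICP diverged: RMS increased over 10 consecutive iterations; ",
             "trace: ", paste(sprintf("%.4g", utils::tail(trace, 12)), collapse = " "))
      if (abs(prev - rms) <= tol * max(prev, 1e-300) || rms < 1e-12) {
        Tcur <- kabsch(mv, q)
        break
      }
    }
    Tcur <- kabsch(mv, q)
  }
  p <- transform_apply(Tcur, mv)
  nn <- nearest_vertex(p, fv)
  list(transform = Tcur, rms = sqrt(mean(nn$dist2)),
       iterations = length(trace), trace = trace)
}

# closed-form least-squares rigid fit p -> q (Kabsch / Umeyama, no scaling)
kabsch <- function(p, q) {
  cp <- colMeans(p); cq <- colMeans(q)
  H <- crossprod(sweep(p, 2, cp), sweep(q, 2, cq))
  s <- svd(H)
  R <- s$v %*% t(s$u)
  if (det(R) < 0) R <- s$v %*% diag(c(1, 1, -1)) %*% t(s$u)
  rigid_transform(R, cq - drop(R %*% cp))
}

# brute-force nearest target vertex per query point, chunked to bound memory
nearest_vertex <- function(query, target) {
  t2 <- rowSums(target^2)
  n <- nrow(query)
  idx <- integer(n); d2 <- numeric(n)
  chunk <- max(1L, min(n, as.integer(2e7 / nrow(target))))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    qc <- query[s:e, , drop = FALSE]
    D <- sweep(-2 * tcrossprod(qc, target), 2, t2, "+")  # ||t||^2 - 2 q.t
    j <- max.col(-D, ties.method = "first")
    idx[s:e] <- j
    # recompute matched distances directly: the expanded form cancels badly
    d2[s:e] <- rowSums((qc - target[j, , drop = FALSE])^2)
  }
  list(index = idx, dist2 = d2)
}

# logical selector of points inside a region specification
region_select <- function(points, spec) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(is.list(spec), !is.null(spec$type))
  switch(spec$type,
    box = {
      lo <- as.numeric(spec$min); hi <- as.numeric(spec$max)
      points[, 1] >= lo[1] & points[, 1] <= hi[1] &
        points[, 2] >= lo[2] & points[, 2] <= hi[2] &
        points[, 3] >= lo[3] & points[, 3] <= hi[3]
    },
    sphere = {
      ctr <- as.numeric(spec$center)
      rowSums(sweep(points, 2, ctr)^2) <= spec$radius^2
    },
    halfspace = {
      pl <- plane3d(spec$point, spec$normal)
      plane_distance(pl, points) >= 0
    },
    stop("unknown region type: ", spec$type))
}

#' Construct a landmark set
#'
#' Named 3D landmarks used to build the cranial frame. Required names:
#' `origin` (frame origin), `anterior` (with `origin`, fixes the midsagittal
#' X direction), and `axial_1`, `axial_2`, `axial_3` (a triple spanning the
#' axial plane, ordered counter-clockwise seen from cranial). Optional
#' `cranial` disambiguates the Z sign.
#'
#' @param ... named length-3 numeric landmarks, or a single named list.
#' @return Object of class `landmark_set` (a named list of points).
#' @export
landmark_set <- function(...) {
  lm <- list(...)
  if (length(lm) == 1L && is.list(lm[[1]]) && is.null(dim(lm[[1]])))
    lm <- lm[[1]]
  req <- c("origin", "anterior", "axial_1", "axial_2", "axial_3")
  missing <- setdiff(req, names(lm))
  if (length(missing))
    stop("missing required landmarks: ", paste(missing, collapse = ", "))
  lm <- lapply(lm, as.numeric)
  stopifnot(all(vapply(lm, length, 0L) == 3L))
  pts <- do.call(rbind, lm)
  dd <- as.matrix(stats::dist(pts))
  diag(dd) <- Inf
  if (min(dd) < 0.1)
    stop("coincident landmarks (within 0.1 mm): ",
         paste(names(lm)[which(dd == min(dd), arr.ind = TRUE)[1, ]],
               collapse = " / "))
  structure(lm, class = "landmark_set")
}

#' Build the skull-aligned coordinate frame
#'
#' Z is the normal of the axial landmark triple (oriented cranially), X the
#' anterior direction projected orthogonal to Z, and Y = Z x X
#' (left-lateral); the origin is the `origin` landmark. The result is
#' orthonormal and right-handed (x cross y = z).
#'
#' @param landmarks a [landmark_set()].
#' @return Object of class `cranial_frame` with `origin`, `axis_x`,
#'   `axis_y`, `axis_z`.
#' @export
build_frame <- function(landmarks) {
  if (!inherits(landmarks, "landmark_set")) landmarks <- landmark_set(landmarks)
  a1 <- landmarks$axial_1; a2 <- landmarks$axial_2; a3 <- landmarks$axial_3
  zn <- cross3(a2 - a1, a3 - a1)
  if (sqrt(sum(zn^2)) < 1e-6 * max(1, sqrt(sum((a2 - a1)^2))))
    stop("degenerate frame: axial landmark triple is collinear")
  z <- unit3(zn)
  if (!is.null(landmarks$cranial) &&
      sum(z * (landmarks$cranial - landmarks$origin)) < 0) z <- -z
  ant <- landmarks$anterior - landmarks$origin
  xr <- ant - sum(ant * z) * z
  if (sqrt(sum(xr^2)) < 1e-9)
    stop("degenerate frame: anterior direction parallel to axial normal")
  x <- unit3(xr)
  y <- cross3(z, x)
  structure(list(origin = landmarks$origin, axis_x = x, axis_y = y, axis_z = z),
            class = "cranial_frame")
}

#' @export
print.cranial_frame <- function(x, ...) {
  cat("<cranial_frame>\n")
  cat(sprintf("  origin: (%.3f, %.3f, %.3f)\n", x$origin[1], x$origin[2], x$origin[3]))
  for (ax in c("axis_x", "axis_y", "axis_z"))
    cat(sprintf("  %s: (%.4f, %.4f, %.4f)\n", ax, x[[ax]][1], x[[ax]][2], x[[ax]][3]))
  invisible(x)
}

#' Express a mesh or point in frame coordinates
#'
#' Rigid change of coordinates: the frame origin maps to (0,0,0) and the
#' frame axes to the canonical axes. Distances and volumes are preserved.
#'
#' @param x a [surface_mesh()], an n x 3 matrix, or a length-3 point.
#' @param frame a [cranial_frame()].
#' @return `x` in frame coordinates.
#' @export
to_frame <- function(x, frame) {
  transform_apply(frame_transform(frame), x)
}

#' The rigid transform from world to frame coordinates
#'
#' @param frame a [cranial_frame()].
#' @return A [rigid_transform()] `t` with `transform_apply(t, frame$origin) == c(0,0,0)`.
#' @export
frame_transform <- function(frame) {
  R <- rbind(frame$axis_x, frame$axis_y, frame$axis_z)
  dimnames(R) <- NULL
  rigid_transform(R, drop(-R %*% frame$origin))
}

#' Midsagittal plane of a frame
#'
#' The XZ-plane of the cranial frame: through the frame origin with normal
#' along the left-lateral Y axis.
#'
#' @param frame a [cranial_frame()].
#' @return A [plane3d()].
#' @export
midsagittal_plane <- function(frame) {
  plane3d(frame$origin, frame$axis_y)
}
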