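# Synthetic test worlds with known ground truth: schematic bone phantoms
# (skull shell + asymmetry bump, condylar ellipsoids, symphyseal arch) under
# known per-region rigid motions, airway tubes of revolution with controlled
# radius profiles, and cohort generation with a stated rank correlation
# between symphysis setback and hypopharyngeal minCSA change. Shapes are
# schematic, not anatomical: the validation surface is geometric recovery.

# run code with a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit(if (has) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

# ---- mesh primitives -------------------------------------------------------

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to a sphere; watertight, outward
#' orientation.
#'
#' @param radius sphere radius in mm.
#' @param center length-3 center.
#' @param subdivisions subdivision level (0 = icosahedron, 20 faces;
#'   each level quadruples the face count).
#' @return A [surface_mesh()].
#' @export
icosphere <- function(radius = 1, center = c(0, 0, 0), subdivisions = 3L) {
  tt <- (1 + sqrt(5)) / 2
  v <- matrix(c(-1, tt, 0,  1, tt, 0,  -1, -tt, 0,  1, -tt, 0,
                0, -1, tt,  0, 1, tt,  0, -1, -tt,  0, 1, -tt,
                tt, 0, -1,  tt, 0, 1,  -tt, 0, -1,  -tt, 0, 1),
              ncol = 3, byrow = TRUE)
  f <- matrix(c(1,12,6, 1,6,2, 1,2,8, 1,8,11, 1,11,12,
                2,6,10, 6,12,5, 12,11,3, 11,8,7, 8,2,9,
                4,10,5, 4,5,3, 4,3,7, 4,7,9, 4,9,10,
                5,10,6, 3,5,12, 7,3,11, 9,7,8, 10,9,2),
              ncol = 3, byrow = TRUE)
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdivisions)) {
    sub <- subdivide_faces(v, f)
    v <- sub$v / sqrt(rowSums(sub$v^2))
    f <- sub$f
  }
  surface_mesh(sweep(v * radius, 2, center, "+"), f, name = "icosphere")
}

# one 4:1 loop subdivision step with midpoint dedup by edge key
subdivide_faces <- function(v, f) {
  nf <- nrow(f); nv <- nrow(v)
  a <- c(f[, 1], f[, 2], f[, 3]); b <- c(f[, 2], f[, 3], f[, 1])
  key <- pmin(a, b) * (nv + 1) + pmax(a, b)
  uk <- unique(key)
  mid_id <- nv + match(key, uk)
  first <- match(uk, key)
  mids <- (v[a[first], , drop = FALSE] + v[b[first], , drop = FALSE]) / 2
  m1 <- mid_id[seq_len(nf)]
  m2 <- mid_id[nf + seq_len(nf)]
  m3 <- mid_id[2 * nf + seq_len(nf)]
  list(v = rbind(v, mids),
       f = rbind(cbind(f[, 1], m1, m3), cbind(f[, 2], m2, m1),
                 cbind(f[, 3], m3, m2), cbind(m1, m2, m3)))
}

#' Ellipsoid mesh
#'
#' @param semi_axes length-3 semi-axis lengths in mm.
#' @param center length-3 center.
#' @param rotation optional 3x3 rotation applied to the axes.
#' @param subdivisions icosphere subdivision level.
#' @return A [surface_mesh()].
#' @export
ellipsoid_mesh <- function(semi_axes, center = c(0, 0, 0), rotation = diag(3),
                           subdivisions = 3L) {
  s <- icosphere(1, c(0, 0, 0), subdivisions)
  v <- sweep(s$vertices, 2, as.numeric(semi_axes), "*") %*% t(rotation)
  surface_mesh(sweep(v, 2, center, "+"), s$faces, name = "ellipsoid")
}

#' Tube of revolution along Z
#'
#' Capped, watertight surface of revolution about the Z axis with a
#' z-dependent radius.
#'
#' @param radius_fun function of z returning the radius in mm (vectorized or
#'   not); must be strictly positive over the z range.
#' @param z_from,z_to axial extent in mm.
#' @param segments circumferential segments (default 128, which puts the
#'   polygon-vs-circle area deficit near 0.04%).
#' @param ring_mm axial ring spacing in mm.
#' @param center_xy in-plane center of the axis.
#' @return A [surface_mesh()].
#' @export
tube_mesh <- function(radius_fun, z_from, z_to, segments = 128L,
                      ring_mm = 1, center_xy = c(0, 0)) {
  zs <- seq(z_from, z_to, length.out = max(2L, ceiling((z_to - z_from) / ring_mm) + 1L))
  r <- vapply(zs, function(z) as.numeric(radius_fun(z)), numeric(1))
  if (any(!is.finite(r)) || any(r <= 0))
    stop("non-positive radius in tube profile")
  nr <- length(zs); ns <- as.integer(segments)
  ang <- 2 * pi * (seq_len(ns) - 1L) / ns
  v <- cbind(center_xy[1] + rep(r, each = ns) * cos(ang),
             center_xy[2] + rep(r, each = ns) * sin(ang),
             rep(zs, each = ns))
  id <- function(i, j) (i - 1L) * ns + j          # ring i, angle slot j
  j <- seq_len(ns); jn <- c(2:ns, 1L)
  fa <- do.call(rbind, lapply(seq_len(nr - 1L), function(i) {
    a <- id(i, j); b <- id(i, jn); cc <- id(i + 1L, jn); d <- id(i + 1L, j)
    rbind(cbind(a, b, cc), cbind(a, cc, d))
  }))
  cb <- nrow(v) + 1L; ct <- nrow(v) + 2L
  v <- rbind(v, c(center_xy, zs[1]), c(center_xy, zs[nr]))
  caps <- rbind(cbind(cb, id(1L, jn), id(1L, j)),        # bottom faces -z
                cbind(ct, id(nr, j), id(nr, jn)))        # top faces +z
  surface_mesh(v, rbind(fa, caps), name = "tube")
}

#' Cylinder mesh
#'
#' @param radius cylinder radius in mm.
#' @param z_from,z_to axial extent.
#' @param segments circumferential segments.
#' @param ring_mm axial ring spacing.
#' @return A [surface_mesh()].
#' @export
cylinder_mesh <- function(radius, z_from, z_to, segments = 128L, ring_mm = 5) {
  m <- tube_mesh(function(z) radius, z_from, z_to, segments, ring_mm)
  m$name <- "cylinder"
  m
}

#' Torus mesh
#'
#' Torus about the Z axis (watertight, outward orientation).
#'
#' @param major_radius,minor_radius torus radii in mm.
#' @param segments_major,segments_minor tessellation.
#' @param center length-3 center.
#' @return A [surface_mesh()].
#' @export
torus_mesh <- function(major_radius = 10, minor_radius = 3,
                       segments_major = 48L, segments_minor = 24L,
                       center = c(0, 0, 0)) {
  nu <- as.integer(segments_major); nv <- as.integer(segments_minor)
  u <- 2 * pi * (seq_len(nu) - 1L) / nu
  vv <- 2 * pi * (seq_len(nv) - 1L) / nv
  rr <- major_radius + minor_radius * cos(rep(vv, times = nu))
  verts <- cbind(rr * cos(rep(u, each = nv)),
                 rr * sin(rep(u, each = nv)),
                 minor_radius * sin(rep(vv, times = nu)))
  id <- function(i, j) (i - 1L) * nv + j          # ring i (major), slot j (minor)
  i <- rep(seq_len(nu), each = nv); j <- rep(seq_len(nv), times = nu)
  inx <- i %% nu + 1L; jnx <- j %% nv + 1L
  a <- id(i, j); b <- id(inx, j); cc <- id(inx, jnx); d <- id(i, jnx)
  f <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  surface_mesh(sweep(verts, 2, center, "+"), f, name = "torus")
}

#' Swept-arch mesh (schematic symphysis)
#'
#' A rectangular cross-section swept along a circular arc about the Z axis:
#' the schematic stand-in for the symphyseal (or fibular neo-symphyseal)
#' region, crossing the midsagittal plane.
#'
#' @param inner_radius,outer_radius radial extent of the rectangle, mm.
#' @param z_min,z_max vertical extent, mm.
#' @param angle_deg length-2 arc angular range in degrees, measured from the
#'   +X axis toward +Y.
#' @param segments arc segments.
#' @return A watertight [surface_mesh()].
#' @export
arch_mesh <- function(inner_radius = 45, outer_radius = 55, z_min = -100,
                      z_max = -85, angle_deg = c(-40, 40), segments = 24L) {
  ns <- as.integer(segments)
  th <- seq(angle_deg[1], angle_deg[2], length.out = ns + 1L) * pi / 180
  # cross-section corners in (radial, z), CCW about the sweep tangent
  corners <- cbind(r = c(inner_radius, outer_radius, outer_radius, inner_radius),
                   z = c(z_min, z_min, z_max, z_max))
  nv_ring <- 4L
  v <- do.call(rbind, lapply(th, function(t)
    cbind(corners[, "r"] * cos(t), corners[, "r"] * sin(t), corners[, "z"])))
  id <- function(i, j) (i - 1L) * nv_ring + j
  j <- seq_len(nv_ring); jn <- c(2:nv_ring, 1L)
  fa <- do.call(rbind, lapply(seq_len(ns), function(i) {
    a <- id(i, j); b <- id(i, jn); cc <- id(i + 1L, jn); d <- id(i + 1L, j)
    rbind(cbind(a, b, cc), cbind(a, cc, d))
  }))
  caps <- rbind(cbind(id(1L, 1L), id(1L, 3L), id(1L, 2L)),
                cbind(id(1L, 1L), id(1L, 4L), id(1L, 3L)),
                cbind(id(ns + 1L, 1L), id(ns + 1L, 2L), id(ns + 1L, 3L)),
                cbind(id(ns + 1L, 1L), id(ns + 1L, 3L), id(ns + 1L, 4L)))
  m <- surface_mesh(v, rbind(fa, caps), name = "arch")
  if (mesh_volume_unchecked(m) < 0) m$faces <- m$faces[, c(1L, 3L, 2L)]
  m
}

# signed volume without the watertightness gate (orientation probe)
mesh_volume_unchecked <- function(mesh) {
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  sum(rowSums(v1 * face_cross(mesh))) / 6
}

#' Concatenate meshes into one multi-component mesh
#'
#' Components stay disjoint closed shells; the result is watertight if every
#' component is, and [mesh_volume()] sums the component volumes.
#'
#' @param meshes list of [surface_mesh()] objects.
#' @param name label for the result.
#' @return A `surface_mesh`.
#' @export
concat_meshes <- function(meshes, name = "combined") {
  off <- 0L
  vs <- list(); fs <- list()
  for (m in meshes) {
    vs[[length(vs) + 1L]] <- m$vertices
    fs[[length(fs) + 1L]] <- m$faces + off
    off <- off + nrow(m$vertices)
  }
  surface_mesh(do.call(rbind, vs), do.call(rbind, fs), name = name,
               drop_degenerate = FALSE)
}

# ---- phantom layout and truth ---------------------------------------------

#' Phantom layout constants
#'
#' The fixed schematic anatomy of the bone phantom, in cranial-frame
#' coordinates: component positions, landmark set, region specifications for
#' cropping, and airway plane offsets. Shared by the generator, the pipeline
#' configuration and the tests.
#'
#' @return Named list: `condyle_centers`, `landmarks`, `regions` (skull_mask,
#'   condyle_left, condyle_right, symphysis), `airway` (plane z-offsets and
#'   tube extent).
#' @export
phantom_geometry <- function() {
  list(
    skull = list(semi_axes = c(70, 55, 55), center = c(0, 0, 20),
                 bump_center = c(85, 25, 45), bump_radius = 10),
    condyle_centers = list(left = c(-45, 85, -20), right = c(-45, -85, -20)),
    condyle_semi_axes = c(6, 9, 12),
    # offset knob breaking the ellipsoid's 180-degree flip symmetry: without
    # it the condylar pose is not identifiable from the mesh alone
    condyle_bump = list(offset = c(7, 6, 9), radius = 2.5),
    arch = list(inner_radius = 45, outer_radius = 55, z_min = -100,
                z_max = -85, angle_deg = c(-40, 40)),
    landmarks = landmark_set(
      origin = c(0, 0, 0), anterior = c(80, 0, 0),
      axial_1 = c(60, 0, 0), axial_2 = c(-60, 40, 0), axial_3 = c(-60, -40, 0),
      cranial = c(0, 0, 80)),
    regions = list(
      skull_mask = list(type = "box", min = c(-72, -57, -37), max = c(96, 57, 77)),
      condyle_left = list(type = "sphere", center = c(-45, 85, -20), radius = 16),
      condyle_right = list(type = "sphere", center = c(-45, -85, -20), radius = 16),
      symphysis = list(type = "box", min = c(10, -60, -125), max = c(80, 60, -63))),
    airway = list(top = 35, naso_oro = 20, e_plane = 0, bottom = -25,
                  z_from = -30, z_to = 40))
}

#' Rigid transform acting about a point
#'
#' Convenience for phantom truths: rotate about `center`, then translate.
#'
#' @param rotation 3x3 rotation matrix.
#' @param center point the rotation acts about.
#' @param translation additional translation.
#' @return A [rigid_transform()] with
#'   `p -> R (p - center) + center + translation`.
#' @export
about_point <- function(rotation, center, translation = c(0, 0, 0)) {
  center <- as.numeric(center)
  rigid_transform(rotation, center + as.numeric(translation) -
                    drop(rotation %*% center))
}

#' Airway radius profile
#'
#' Constant-radius pharyngeal tube with an optional Gaussian waist (a local
#' narrowing emulating the retro-epiglottic constriction):
#' `r(z) = scale * (base - (base - waist_min) * exp(-(z - waist_center)^2 / (2 waist_sigma^2)))`.
#'
#' @param base baseline radius, mm.
#' @param waist_min minimum radius at the waist, mm (`NULL` for none).
#' @param waist_center,waist_sigma waist location and width along z, mm.
#' @param scale global radial scale factor.
#' @return A function of z returning the radius.
#' @export
radius_profile <- function(base = 5, waist_min = NULL, waist_center = -15,
                           waist_sigma = 5, scale = 1) {
  if (is.null(waist_min)) return(function(z) scale * base + 0 * z)
  stopifnot(waist_min > 0, waist_min <= base)
  function(z)
    scale * (base - (base - waist_min) * exp(-(z - waist_center)^2 / (2 * waist_sigma^2)))
}

#' Phantom ground truth
#'
#' @param condyle_left,condyle_right absolute [rigid_transform()]s (cranial
#'   frame) applied to the condyles between timepoints; see [about_point()].
#' @param symphysis_shift length-2 `(s_dx, s_dz)` translation of the
#'   symphysis in mm (negative `s_dx` = posterior, setback-like).
#' @param airway_pre,airway_post radius profiles (see [radius_profile()]).
#' @param noise_sd Gaussian vertex noise, mm (applied independently to pre
#'   and post meshes).
#' @param seed integer seed; a fixed seed reproduces byte-identical phantoms.
#' @param segments,ring_mm,subdivisions,arch_segments mesh resolution.
#' @return Object of class `phantom_truth`.
#' @export
phantom_truth <- function(condyle_left = rigid_transform(),
                          condyle_right = rigid_transform(),
                          symphysis_shift = c(0, 0),
                          airway_pre = radius_profile(5, waist_min = 3),
                          airway_post = radius_profile(5, waist_min = 3),
                          noise_sd = 0, seed = 1L,
                          segments = 128L, ring_mm = 1, subdivisions = 3L,
                          arch_segments = 24L) {
  stopifnot(noise_sd >= 0, length(symphysis_shift) == 2L)
  structure(list(condyle_left = condyle_left, condyle_right = condyle_right,
                 symphysis_shift = as.numeric(symphysis_shift),
                 airway_pre = airway_pre, airway_post = airway_post,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 segments = as.integer(segments), ring_mm = ring_mm,
                 subdivisions = as.integer(subdivisions),
                 arch_segments = as.integer(arch_segments)),
            class = "phantom_truth")
}

add_vertex_noise <- function(mesh, sd) {
  if (sd <= 0) return(mesh)
  mesh$vertices <- mesh$vertices +
    matrix(stats::rnorm(length(mesh$vertices), 0, sd), ncol = 3)
  mesh
}

#' Generate the bone phantom
#'
#' Pre- and post-operative bone meshes: skull shell with asymmetry bump
#' (unchanged — the registration anchor), left/right condylar ellipsoids
#' moved by the truth transforms, and the symphyseal arch translated by
#' `(s_dx, 0, s_dz)`. Optional vertex noise. Components are checked for
#' interpenetration of their bounding spheres (warning only).
#'
#' @param truth a [phantom_truth()].
#' @return List: `pre`, `post` (combined `surface_mesh`), `components`
#'   (per-region meshes), `landmarks`, `regions`, `truth`.
#' @export
make_bone_phantom <- function(truth) {
  g <- phantom_geometry()
  sub <- truth$subdivisions
  skull <- concat_meshes(list(
    ellipsoid_mesh(g$skull$semi_axes, g$skull$center, subdivisions = sub),
    icosphere(g$skull$bump_radius, g$skull$bump_center,
              subdivisions = max(1L, sub - 1L))), name = "skull")
  cond <- lapply(g$condyle_centers, function(ctr) concat_meshes(list(
    ellipsoid_mesh(g$condyle_semi_axes, ctr, subdivisions = max(1L, sub - 1L)),
    icosphere(g$condyle_bump$radius, ctr + g$condyle_bump$offset,
              subdivisions = max(1L, sub - 1L))), name = "condyle"))
  arch <- arch_mesh(g$arch$inner_radius, g$arch$outer_radius, g$arch$z_min,
                    g$arch$z_max, g$arch$angle_deg, truth$arch_segments)
  shift <- rigid_transform(diag(3),
                           c(truth$symphysis_shift[1], 0, truth$symphysis_shift[2]))
  post_comp <- list(skull = skull,
                    condyle_left = transform_apply(truth$condyle_left, cond$left),
                    condyle_right = transform_apply(truth$condyle_right, cond$right),
                    symphysis = transform_apply(shift, arch))
  pre_comp <- list(skull = skull, condyle_left = cond$left,
                   condyle_right = cond$right, symphysis = arch)
  check_interpenetration(post_comp)
  if (truth$noise_sd > 0) {
    pre_comp <- with_seed(truth$seed, lapply(pre_comp, add_vertex_noise,
                                             sd = truth$noise_sd))
    post_comp <- with_seed(truth$seed + 1L, lapply(post_comp, add_vertex_noise,
                                                   sd = truth$noise_sd))
  }
  list(pre = concat_meshes(pre_comp, "bone_pre"),
       post = concat_meshes(post_comp, "bone_post"),
       components = list(pre = pre_comp, post = post_comp),
       landmarks = g$landmarks, regions = g$regions, truth = truth)
}

check_interpenetration <- function(comp) {
  ctr <- t(vapply(comp, function(m) colMeans(m$vertices), numeric(3)))
  rad <- vapply(seq_along(comp), function(i)
    sqrt(max(rowSums(sweep(comp[[i]]$vertices, 2, ctr[i, ])^2))), numeric(1))
  nn <- length(comp)
  for (i in seq_len(nn - 1L)) for (j in (i + 1L):nn) {
    if (sqrt(sum((ctr[i, ] - ctr[j, ])^2)) < 0.5 * (rad[i] + rad[j]))
      warning("phantom regions '", names(comp)[i], "' and '", names(comp)[j],
              "' may interpenetrate after transform")
  }
  invisible(NULL)
}

#' Generate the airway phantom
#'
#' Pre- and post-operative airway lumens as tubes of revolution along the
#' frame Z axis with the truth radius profiles, plus the four reference
#' planes at the layout's offsets (normals cranial).
#'
#' @param truth a [phantom_truth()].
#' @return List: `pre`, `post` (`surface_mesh`), `planes`
#'   ([airway_planes()]), `truth`.
#' @export
make_airway_phantom <- function(truth) {
  g <- phantom_geometry()$airway
  mk <- function(fun, tag, seed_off) {
    m <- tube_mesh(fun, g$z_from, g$z_to, truth$segments, truth$ring_mm)
    m$name <- paste0("airway_", tag)
    if (truth$noise_sd > 0)
      m <- with_seed(truth$seed + seed_off, add_vertex_noise(m, truth$noise_sd))
    m
  }
  zplane <- function(z) plane3d(c(0, 0, z), c(0, 0, 1))
  list(pre = mk(truth$airway_pre, "pre", 1000L),
       post = mk(truth$airway_post, "post", 2000L),
       planes = airway_planes(zplane(g$top), zplane(g$naso_oro),
                              zplane(g$e_plane), zplane(g$bottom)),
       truth = truth)
}

# ---- cohort generation -----------------------------------------------------

#' Cohort specification
#'
#' The stated synthetic world for cohort simulations: per-subject symphysis
#' setback `s_dx ~ Normal(location, scale)` (negative = posterior), a target
#' Spearman correlation (`coupling`) between `s_dx` and the hypopharyngeal
#' minCSA percentage change, and independent Gaussian nuisance on the latent
#' airway response. Defaults emulate the clinical scale: posterior-dominant
#' setback with median magnitude near 8 mm, airway response centred near an
#' 87% area/volume ratio.
#'
#' @param n number of subjects (>= 4).
#' @param coupling target Spearman correlation, |coupling| <= 1.
#' @param setback_location,setback_scale Normal parameters of `s_dx`, mm.
#' @param nuisance_sd independent latent noise scale (relative to the unit
#'   latent); attenuates the attainable coupling.
#' @param effect_log_sd standard deviation of the log radial scale factor.
#' @param effect_log_mean mean of the log radial scale factor (default
#'   `log(sqrt(0.87))`: median area ratio 87%).
#' @param seed integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 35L, coupling = 0.9, setback_location = -7.9,
                        setback_scale = 5, nuisance_sd = 0.3,
                        effect_log_sd = 0.15,
                        effect_log_mean = log(sqrt(0.87)), seed = 1L) {
  stopifnot(n >= 4L, abs(coupling) <= 1, nuisance_sd >= 0, effect_log_sd > 0)
  atten <- 1 / sqrt(1 + nuisance_sd^2)
  rho_req <- 2 * sin(pi * coupling / 6) / atten
  if (abs(rho_req) > 1) {
    bound <- (6 / pi) * asin(atten / 2)
    stop(sprintf(paste0("coupling %.3f infeasible with nuisance_sd %.3f: ",
                        "attainable |Spearman| bound is %.3f"),
                 coupling, nuisance_sd, bound))
  }
  structure(list(n = as.integer(n), coupling = coupling,
                 setback_location = setback_location,
                 setback_scale = setback_scale, nuisance_sd = nuisance_sd,
                 effect_log_sd = effect_log_sd,
                 effect_log_mean = effect_log_mean,
                 rho_pearson = rho_req, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with known truth
#'
#' Draws per-subject setbacks and airway radial scale factors from a Gaussian
#' copula whose Pearson correlation is `2*sin(pi*coupling/6)` (corrected for
#' the nuisance attenuation), so the population Spearman correlation between
#' `s_dx` and the minCSA percentage change equals `coupling`. Small random
#' condylar motions (rotations SD 2 deg, translations SD 1.5 mm) emulate the
#' clinical scale of condylar deviation.
#'
#' @param spec a [cohort_spec()].
#' @param segments,ring_mm,subdivisions,arch_segments per-subject phantom
#'   resolution (cohort default is coarser than the single-case default to
#'   bound runtime; the polygon area deficit at 64 segments is ~0.16%, far
#'   below the between-subject spread).
#' @return List: `truths` (list of [phantom_truth()]), `table` (data frame
#'   with per-subject ground truth: `id`, `s_dx`, `s_dz`, `radius_scale`,
#'   `expected_min_csa_pct`, `expected_volume_pct`), `spec`.
#' @export
make_cohort <- function(spec, segments = 64L, ring_mm = 2,
                        subdivisions = 2L, arch_segments = 16L) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  draws <- with_seed(spec$seed, {
    u <- stats::rnorm(n)
    e <- stats::rnorm(n)
    eta <- stats::rnorm(n)
    s_dz <- stats::rnorm(n, 0, 1.5)
    rots <- matrix(stats::rnorm(6 * n, 0, 2), ncol = 6)
    trans <- matrix(stats::rnorm(6 * n, 0, 1.5), ncol = 6)
    list(u = u, e = e, eta = eta, s_dz = s_dz, rots = rots, trans = trans)
  })
  rho <- spec$rho_pearson
  w <- rho * draws$u + sqrt(1 - rho^2) * draws$e
  w_tot <- (w + spec$nuisance_sd * draws$eta) / sqrt(1 + spec$nuisance_sd^2)
  s_dx <- spec$setback_location + spec$setback_scale * draws$u
  f <- exp(spec$effect_log_mean + spec$effect_log_sd * w_tot)
  g <- phantom_geometry()
  truths <- lapply(seq_len(n), function(i) {
    cl <- about_point(rotation_from_euler(draws$rots[i, 1], draws$rots[i, 2],
                                          draws$rots[i, 3]),
                      g$condyle_centers$left, draws$trans[i, 1:3])
    cr <- about_point(rotation_from_euler(draws$rots[i, 4], draws$rots[i, 5],
                                          draws$rots[i, 6]),
                      g$condyle_centers$right, draws$trans[i, 4:6])
    phantom_truth(condyle_left = cl, condyle_right = cr,
                  symphysis_shift = c(s_dx[i], draws$s_dz[i]),
                  airway_pre = radius_profile(5, waist_min = 3),
                  airway_post = radius_profile(5, waist_min = 3, scale = f[i]),
                  seed = spec$seed + i,
                  segments = segments, ring_mm = ring_mm,
                  subdivisions = subdivisions, arch_segments = arch_segments)
  })
  table <- data.frame(id = sprintf("P%03d", seq_len(n)),
                      s_dx = s_dx, s_dz = draws$s_dz, radius_scale = f,
                      expected_min_csa_pct = 100 * f^2,
                      expected_volume_pct = 100 * f^2)
  list(truths = truths, table = table, spec = spec)
}

#' Write a phantom case to disk as standard pipeline inputs
#'
#' Writes the four STL meshes, the landmark/region/plane configuration as
#' JSON and the ground-truth row as CSV, so a phantom case is
#' indistinguishable from a real segmented case to the pipeline.
#'
#' @param truth a [phantom_truth()].
#' @param dir output directory (created if needed).
#' @param id case identifier used in file names.
#' @return The [patient_case()], with file paths, invisibly.
#' @export
write_phantom_case <- function(truth, dir, id = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bone <- make_bone_phantom(truth)
  air <- make_airway_phantom(truth)
  paths <- list(pre_skull = file.path(dir, paste0(id, "_bone_pre.stl")),
                post_skull = file.path(dir, paste0(id, "_bone_post.stl")),
                pre_airway = file.path(dir, paste0(id, "_airway_pre.stl")),
                post_airway = file.path(dir, paste0(id, "_airway_post.stl")))
  write_stl(bone$pre, paths$pre_skull)
  write_stl(bone$post, paths$post_skull)
  write_stl(air$pre, paths$pre_airway)
  write_stl(air$post, paths$post_airway)
  cfgp <- file.path(dir, paste0(id, "_config.json"))
  write_pipeline_config(phantom_config(), cfgp)
  utils::write.csv(data.frame(id = id,
                              s_dx = truth$symphysis_shift[1],
                              s_dz = truth$symphysis_shift[2]),
                   file.path(dir, paste0(id, "_truth.csv")), row.names = FALSE)
  invisible(patient_case(id = id, pre_skull = paths$pre_skull,
                         post_skull = paths$post_skull,
                         pre_airway = paths$pre_airway,
                         post_airway = paths$post_airway,
                         config = cfgp))
}
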