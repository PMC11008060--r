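# STL I/O, volumetry, sectioning, clipping

test_that("STL round trips preserve geometry and clean up duplicates", {
  p <- withr::local_tempfile(fileext = ".stl")
  ascii_cube_stl(p)
  cube <- read_stl(p, quiet = TRUE)
  expect_equal(nrow(cube$vertices), 8L)   # 36 facet vertices welded to 8
  expect_equal(nrow(cube$faces), 12L)
  expect_equal(mesh_volume(cube), 1.0, tolerance = 1e-12)

  # binary round trip: float32 precision
  m <- icosphere(7.3, center = c(1.2, -4.5, 6.7), subdivisions = 2)
  pb <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, pb)
  m2 <- read_stl(pb, quiet = TRUE)
  expect_equal(nrow(m2$vertices), nrow(m$vertices))
  # welding may reorder vertices: compare as point sets (Hausdorff)
  d2 <- outer(rowSums(m$vertices^2), rowSums(m2$vertices^2), "+") -
    2 * tcrossprod(m$vertices, m2$vertices)
  expect_lt(sqrt(max(pmax(apply(d2, 1, min), 0))), 1e-5)
  expect_equal(mesh_volume(m2), mesh_volume(m), tolerance = 1e-5)

  # coincident duplicate facet: one retained, cleanup reported
  tri <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), ncol = 3, byrow = TRUE)
  dup <- surface_mesh(rbind(tri, tri), rbind(c(1, 2, 3), c(4, 5, 6)))
  pd <- withr::local_tempfile(fileext = ".stl")
  write_stl(dup, pd)
  expect_message(md <- read_stl(pd), "dropped 1 faces")
  expect_equal(nrow(md$faces), 1L)
})

test_that("corrupt STL inputs fail with format errors", {
  pb <- withr::local_tempfile(fileext = ".stl")
  write_stl(icosphere(5, subdivisions = 1), pb)
  raw <- readBin(pb, "raw", file.info(pb)$size)
  writeBin(raw[1:(length(raw) - 37)], pb)   # truncate mid-facet
  expect_error(read_stl(pb), "truncated binary STL")
  expect_error(read_stl(tempfile()), "not found")
})

test_that("mesh_volume is analytic, rigid-invariant and guards watertightness", {
  s <- icosphere(10, subdivisions = 4)
  expect_equal(mesh_volume(s), 4188.79, tolerance = 0.005)
  # convergence across subdivision levels (inscribed: increasing toward 4/3 pi r^3)
  vols <- vapply(2:4, function(k) mesh_volume(icosphere(10, subdivisions = k)),
                 numeric(1))
  expect_true(all(diff(vols) > 0))
  expect_true(all(vols < 4 / 3 * pi * 1000))

  tr <- rigid_transform(rotation_from_euler(33, -41, 97), c(12, -7, 3))
  expect_equal(mesh_volume(transform_apply(tr, s)), mesh_volume(s),
               tolerance = 1e-9)

  open <- s
  open$faces <- open$faces[-(1:3), ]
  expect_error(mesh_volume(open), "boundary edges")
})

test_that("volume QC flags segmentation volume mismatch at its tolerance", {
  s1 <- icosphere(10, subdivisions = 3)
  same <- volume_qc(s1, s1, tolerance = 0.02)
  expect_true(same$pass)
  expect_equal(same$ratio, 1.0)

  s2 <- icosphere(10.2, subdivisions = 3)
  qc <- volume_qc(s1, s2, tolerance = 0.02)
  expect_false(qc$pass)                      # (10.2/10)^3 ~ 1.061
  expect_equal(qc$ratio, 1.02^3, tolerance = 1e-9)
  expect_true(volume_qc(s1, s2, tolerance = 0.07)$pass)
})

face_centroid_x <- function(m)
  (m$vertices[m$faces[, 1], 1] + m$vertices[m$faces[, 2], 1] +
     m$vertices[m$faces[, 3], 1]) / 3

test_that("plane sections chain into closed loops with correct topology", {
  cy <- cylinder_mesh(5, -10, 10, segments = 128)
  ct <- section_with_plane(cy, plane3d(c(0, 0, 0), c(0, 0, 1)))
  expect_length(ct$loops, 1L)
  expect_equal(contour_area(ct), 25 * pi, tolerance = 0.005)
  # all section points on the plane
  expect_lt(max(abs(ct$loops[[1]][, 3])), 1e-6)

  to <- torus_mesh(10, 3)
  ct2 <- section_with_plane(to, plane3d(c(0, 0, 0), c(1, 0, 0)))
  expect_length(ct2$loops, 2L)

  expect_error(section_with_plane(cy, plane3d(c(0, 0, 50), c(0, 0, 1))),
               "empty contour")
  # open cut of a non-watertight mesh is an error reporting endpoints
  half <- cy
  half$faces <- half$faces[face_centroid_x(half) > 0, ]
  expect_error(section_with_plane(half, plane3d(c(0, 0, 0), c(0, 0, 1))),
               "open section chains")
})

test_that("contour area handles multiple loops, holes and modes", {
  pl <- plane3d(c(0, 0, 0), c(0, 0, 1))
  two <- manual_contour(list(square_loop(c(0, 0, 0), 1),
                             square_loop(c(5, 0, 0), 2)), pl)
  expect_equal(contour_area(two, "sum"), 5.0)
  expect_equal(contour_area(two, "largest"), 4.0)

  ann <- manual_contour(list(circle_loop(3), circle_loop(1)), pl)
  expect_equal(contour_area(ann, "sum"), 8 * pi, tolerance = 0.005)

  # sectioned hollow cylinder: even-odd subtracts the island
  hollow <- concat_meshes(list(cylinder_mesh(3, -5, 5, 128),
                               reverse_faces(cylinder_mesh(1, -5, 5, 128))))
  expect_equal(mesh_volume(hollow), 80 * pi, tolerance = 0.005)
  sect <- section_with_plane(hollow, pl)
  expect_length(sect$loops, 2L)
  expect_equal(contour_area(sect, "sum"), 8 * pi, tolerance = 0.005)
  expect_equal(contour_area(sect, "largest"), 9 * pi, tolerance = 0.005)

  bow <- manual_contour(list(rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 0),
                                   c(0, 1, 0))), pl)
  expect_error(contour_area(bow, check_simple = TRUE), "self-intersecting")
})

test_that("contour centroid is the area centroid, invariant to traversal", {
  pl <- plane3d(c(0, 0, 2), c(0, 0, 1))
  sq <- manual_contour(list(square_loop(c(1, 0, 2), 2)), pl)
  expect_equal(contour_centroid(sq), c(1, 0, 2), tolerance = 1e-12)

  # L-shape: union of [0,2]x[0,1] and [0,1]x[1,3] (areas 2 and 2)
  L <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 1, 0), c(1, 1, 0),
             c(1, 3, 0), c(0, 3, 0))
  lc <- manual_contour(list(L), plane3d(c(0, 0, 0), c(0, 0, 1)))
  exp_c <- (2 * c(1, 0.5) + 2 * c(0.5, 2)) / 4   # rectangle decomposition
  expect_equal(contour_centroid(lc)[1:2], exp_c, tolerance = 1e-12)

  # invariance to starting vertex and direction
  perm <- rbind(L[c(4:6, 1:3), ])
  revd <- L[rev(seq_len(nrow(L))), ]
  for (alt in list(perm, revd)) {
    ac <- manual_contour(list(alt), plane3d(c(0, 0, 0), c(0, 0, 1)))
    expect_equal(contour_centroid(ac), contour_centroid(lc), tolerance = 1e-9)
  }

  zero <- manual_contour(list(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
                         plane3d(c(0, 0, 0), c(0, 0, 1)))
  expect_error(contour_centroid(zero), "zero enclosed area")
})

test_that("clipping caps cuts and conserves volume under partition", {
  cy <- cylinder_mesh(5, -10, 10, segments = 128, ring_mm = 2)
  mid <- clip_between_planes(cy, plane3d(c(0, 0, -5), c(0, 0, 1)),
                             plane3d(c(0, 0, 5), c(0, 0, -1)))
  expect_equal(mesh_volume(mid), 250 * pi, tolerance = 0.005)

  # planes outside the extent leave the mesh untouched
  far <- clip_between_planes(cy, plane3d(c(0, 0, -50), c(0, 0, 1)),
                             plane3d(c(0, 0, 50), c(0, 0, -1)))
  expect_equal(mesh_volume(far), mesh_volume(cy), tolerance = 1e-12)

  s <- icosphere(10, subdivisions = 4)
  upper <- clip_halfspace(s, plane3d(c(0, 0, 0), c(0, 0, 1)))
  expect_equal(mesh_volume(upper), 2094.4, tolerance = 0.005)

  # conservation: partition at an arbitrary plane
  cut <- plane3d(c(0, 0, 2.7), c(0, 0, 1))
  lo <- clip_halfspace(s, plane3d(cut$point, -cut$normal))
  hi <- clip_halfspace(s, cut)
  expect_equal(mesh_volume(lo) + mesh_volume(hi), mesh_volume(s),
               tolerance = 1e-6)

  expect_error(clip_between_planes(cy, plane3d(c(0, 0, 40), c(0, 0, 1)),
                                   plane3d(c(0, 0, 50), c(0, 0, -1))),
               "empty geometry")
})

test_that("section area is invariant under common rigid motion and continuous in offset", {
  cy <- cylinder_mesh(5, -10, 10, segments = 96)
  pl <- plane3d(c(0, 0, 1.3), c(0, 0, 1))
  a0 <- contour_area(section_with_plane(cy, pl))
  withr::local_seed(11)
  for (i in 1:5) {
    R <- random_rotation()
    tr <- rigid_transform(R, stats::rnorm(3, 0, 20))
    pl_t <- plane3d(transform_apply(tr, pl$point), drop(R %*% pl$normal))
    a1 <- contour_area(section_with_plane(transform_apply(tr, cy), pl_t))
    expect_equal(a1, a0, tolerance = 1e-9)
  }

  # continuity on a smooth waist tube: adjacent 0.1 mm offsets
  tube <- tube_mesh(radius_profile(5, waist_min = 3), -25, 25, segments = 96)
  offs <- seq(-20, -10, by = 0.1)
  areas <- vapply(offs, function(z)
    contour_area(section_with_plane(tube, plane3d(c(0, 0, z), c(0, 0, 1)))),
    numeric(1))
  expect_lt(max(abs(diff(areas))), 1.5)  # bounded slope, no chaining spikes
})
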