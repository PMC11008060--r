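# rigid transforms, ICP superimposition, cranial frame

test_that("Euler decomposition inverts the intrinsic X-Y-Z construction", {
  withr::local_seed(5)
  for (i in 1:500) {
    ang <- c(stats::runif(1, -179, 179), stats::runif(1, -89, 89),
             stats::runif(1, -179, 179))
    R <- rotation_from_euler(ang[1], ang[2], ang[3])
    back <- euler_angles(R)
    expect_equal(unname(back), ang, tolerance = 1e-9, ignore_attr = TRUE)
  }
  # gimbal lock: theta = 90, phi folded into psi and flagged
  Rg <- rotation_from_euler(25, 90, 10)
  ag <- euler_angles(Rg)
  expect_true(attr(ag, "gimbal_lock"))
  expect_equal(unname(ag["phi_x"]), 0)
  expect_equal(rotation_from_euler(ag["phi_x"], ag["theta_y"], ag["psi_z"]),
               Rg, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("transform algebra: composition, inversion, serialization", {
  a <- rigid_transform(rotation_from_euler(10, 20, 30), c(1, -2, 3))
  b <- rigid_transform(rotation_from_euler(-40, 5, 12), c(-7, 0, 4))
  p <- c(2.5, -1, 9)
  expect_equal(transform_apply(transform_compose(a, b), p),
               transform_apply(a, transform_apply(b, p)), tolerance = 1e-12)
  expect_equal(transform_apply(transform_invert(a), transform_apply(a, p)), p,
               tolerance = 1e-12)
  expect_equal(transform_from_matrix(transform_to_matrix(a)), a,
               tolerance = 1e-12)
  expect_error(rigid_transform(diag(3) * 2), "orthonormal")
  expect_error(rigid_transform(diag(c(1, 1, -1))), "proper")
})

test_that("ICP recovers identity and known rigid poses", {
  skull <- make_bone_phantom(phantom_truth())$pre

  self <- register_icp(skull, skull, init = rigid_transform())
  expect_lt(self$rms, 1e-9)
  expect_lte(self$iterations, 5L)
  expect_equal(self$transform$translation, c(0, 0, 0), tolerance = 1e-9)

  T0 <- rigid_transform(rotation_from_euler(12, -20, 25), c(15, -10, 8))
  fit <- register_icp(transform_apply(T0, skull), skull)
  inv <- transform_invert(T0)
  expect_lt(max(abs(fit$transform$translation - inv$translation)), 0.01)
  expect_lt(max(abs(euler_angles(fit$transform$rotation) -
                      euler_angles(inv$rotation))), 0.01)
})

test_that("ICP is left-invariant and tolerant of vertex noise", {
  skull <- make_bone_phantom(phantom_truth())$pre
  T0 <- rigid_transform(rotation_from_euler(5, 8, -10), c(4, 6, -3))
  base <- register_icp(transform_apply(T0, skull), skull)$transform
  Tpre <- rigid_transform(rotation_from_euler(-7, 3, 9), c(-5, 2, 7))
  fit2 <- register_icp(transform_apply(Tpre, transform_apply(T0, skull)),
                       skull)$transform
  comp <- transform_compose(base, transform_invert(Tpre))
  expect_lt(max(abs(fit2$translation - comp$translation)), 0.01)
  expect_lt(max(abs(fit2$rotation - comp$rotation)), 2e-4)

  # 0.2 mm Gaussian noise on both meshes: translation recovery within 0.1 mm
  tn <- phantom_truth(noise_sd = 0.2, seed = 42)
  bn <- make_bone_phantom(tn)  # skull unchanged => truth is identity
  fitn <- register_icp(bn$post, bn$pre,
                       mask_region = phantom_geometry()$regions$skull_mask)
  expect_lt(max(abs(fitn$transform$translation)), 0.1)
})

test_that("ICP guards: insufficient mask", {
  skull <- make_bone_phantom(phantom_truth())$pre
  expect_error(register_icp(skull, skull,
                            mask_region = list(type = "sphere",
                                               center = c(500, 0, 0),
                                               radius = 1)),
               "insufficient masked points")
})

test_that("frame construction is exact, equivariant and guarded", {
  g <- phantom_geometry()
  fr <- build_frame(g$landmarks)
  expect_equal(fr$axis_x, c(1, 0, 0))
  expect_equal(fr$axis_y, c(0, 1, 0))
  expect_equal(fr$axis_z, c(0, 0, 1))
  expect_equal(fr$origin, c(0, 0, 0))

  withr::local_seed(8)
  for (i in 1:20) {
    R <- random_rotation()
    lm2 <- landmark_set(lapply(unclass(g$landmarks),
                               function(p) drop(R %*% p)))
    fr2 <- build_frame(lm2)
    expect_equal(fr2$axis_x, drop(R %*% fr$axis_x), tolerance = 1e-9)
    expect_equal(fr2$axis_y, drop(R %*% fr$axis_y), tolerance = 1e-9)
    expect_equal(fr2$axis_z, drop(R %*% fr$axis_z), tolerance = 1e-9)
    # orthonormal right-handed
    M <- rbind(fr2$axis_x, fr2$axis_y, fr2$axis_z)
    expect_equal(M %*% t(M), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(c(fr2$axis_x[2] * fr2$axis_y[3] - fr2$axis_x[3] * fr2$axis_y[2],
                   fr2$axis_x[3] * fr2$axis_y[1] - fr2$axis_x[1] * fr2$axis_y[3],
                   fr2$axis_x[1] * fr2$axis_y[2] - fr2$axis_x[2] * fr2$axis_y[1]),
                 fr2$axis_z, tolerance = 1e-9)
  }

  bad <- unclass(g$landmarks)
  bad$axial_2 <- c(30, 0, 0); bad$axial_3 <- c(-30, 0, 0)  # collinear with axial_1
  expect_error(build_frame(landmark_set(bad)), "collinear")
  expect_error(landmark_set(origin = c(0, 0, 0), anterior = c(80, 0, 0),
                            axial_1 = c(60, 0, 0), axial_2 = c(60, 0.01, 0),
                            axial_3 = c(-60, -40, 0)), "coincident")
  expect_error(landmark_set(origin = c(0, 0, 0)), "missing required")
})

test_that("to_frame maps landmarks canonically and preserves volume", {
  lm <- landmark_set(origin = c(10, -5, 3), anterior = c(25, -5, 3),
                     axial_1 = c(20, -5, 3), axial_2 = c(0, 10, 3),
                     axial_3 = c(0, -20, 3), cranial = c(10, -5, 40))
  fr <- build_frame(lm)
  expect_equal(to_frame(fr$origin, fr), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(to_frame(fr$origin + fr$axis_x, fr), c(1, 0, 0),
               tolerance = 1e-12)
  s <- icosphere(6, center = c(12, 0, 1), subdivisions = 3)
  expect_equal(mesh_volume(to_frame(s, fr)), mesh_volume(s), tolerance = 1e-9)

  msp <- midsagittal_plane(fr)
  expect_equal(abs(plane_distance(msp, fr$origin)), 0, tolerance = 1e-12)
  expect_equal(msp$normal, fr$axis_y, tolerance = 1e-12)
})
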