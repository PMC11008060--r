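# phantom generators: determinism, ground-truth recovery, cohort calibration

test_that("identity truth with zero noise yields identical pre/post meshes", {
  b <- make_bone_phantom(phantom_truth())
  expect_identical(b$pre$vertices, b$post$vertices)
  expect_identical(b$pre$faces, b$post$faces)
  a <- make_airway_phantom(phantom_truth())
  expect_identical(a$pre$vertices, a$post$vertices)
})

test_that("fixed seeds reproduce byte-identical STL files", {
  tru <- phantom_truth(noise_sd = 0.15, seed = 99,
                       symphysis_shift = c(-4, 1))
  f1 <- withr::local_tempfile(fileext = ".stl")
  f2 <- withr::local_tempfile(fileext = ".stl")
  write_stl(make_bone_phantom(tru)$post, f1)
  write_stl(make_bone_phantom(tru)$post, f2)
  expect_identical(readBin(f1, "raw", file.info(f1)$size),
                   readBin(f2, "raw", file.info(f2)$size))
  # and a different seed changes the bytes
  tru2 <- phantom_truth(noise_sd = 0.15, seed = 100,
                        symphysis_shift = c(-4, 1))
  f3 <- withr::local_tempfile(fileext = ".stl")
  write_stl(make_bone_phantom(tru2)$post, f3)
  expect_false(identical(readBin(f1, "raw", file.info(f1)$size),
                         readBin(f3, "raw", file.info(f3)$size)))
})

test_that("phantom generation does not disturb the caller's RNG stream", {
  set.seed(123); a <- stats::rnorm(1)
  set.seed(123)
  invisible(make_bone_phantom(phantom_truth(noise_sd = 0.1)))
  b <- stats::rnorm(1)
  expect_identical(a, b)
})

test_that("symphysis shift is recovered through the measurement chain", {
  b <- make_bone_phantom(phantom_truth(symphysis_shift = c(-5, 0)))
  g <- phantom_geometry()
  pre_s <- crop_region(b$pre, g$regions$symphysis)
  post_s <- crop_region(b$post, g$regions$symphysis)
  dev <- symphysis_deviation(pre_s, post_s, plane3d(c(0, 0, 0), c(0, 1, 0)))
  expect_equal(dev$s_dx, -5, tolerance = 0.05)
  expect_equal(dev$s_dz, 0, tolerance = 0.05)
})

test_that("airway phantom honors its radius profile analytically", {
  tru <- phantom_truth(airway_pre = radius_profile(5),
                       airway_post = radius_profile(5, scale = 0.9),
                       segments = 128, ring_mm = 2)
  ap <- make_airway_phantom(tru)
  prof <- csa_profile(ap$pre, ap$planes)
  expect_true(all(abs(prof$profile$area_mm2 - 25 * pi) / (25 * pi) < 0.005))
  vp <- airway_volumes(ap$pre, ap$planes, "pre")
  vq <- airway_volumes(ap$post, ap$planes, "post")
  ch <- airway_change(vp, vq)
  expect_equal(unname(ch$volume_pct), rep(81, 4), tolerance = 0.01)

  waisted <- make_airway_phantom(phantom_truth(segments = 96))
  pw <- csa_profile(waisted$pre, waisted$planes)
  expect_equal(pw$min_offset_hypo, -15)
  expect_equal(pw$min_csa_hypo, 9 * pi, tolerance = 0.01)

  expect_error(make_airway_phantom(
    phantom_truth(airway_pre = function(z) 5 - 0.2 * z)),
    "non-positive radius")
})

test_that("recovery error grows with vertex noise", {
  errs <- vapply(c(0, 0.1, 0.3), function(sd) {
    e <- vapply(1:6, function(s) {
      b <- make_bone_phantom(phantom_truth(symphysis_shift = c(-5, 2),
                                           noise_sd = sd, seed = 500 + s,
                                           arch_segments = 16))
      g <- phantom_geometry()
      dev <- symphysis_deviation(
        crop_region(b$pre, g$regions$symphysis),
        crop_region(b$post, g$regions$symphysis),
        plane3d(c(0, 0, 0), c(0, 1, 0)))
      abs(dev$s_dx + 5)
    }, numeric(1))
    mean(e)
  }, numeric(1))
  expect_true(all(diff(errs) >= -1e-9))   # non-decreasing in noise
  expect_lt(errs[1], 1e-9)
})

test_that("cohort coupling calibrates the population rank correlation", {
  big <- make_cohort(cohort_spec(n = 1000, coupling = 0.6, seed = 11))
  emp <- stats::cor(big$table$s_dx, big$table$expected_min_csa_pct,
                    method = "spearman")
  expect_equal(emp, 0.6, tolerance = 0.05)

  zero <- make_cohort(cohort_spec(n = 1000, coupling = 0, seed = 12))
  expect_lt(abs(stats::cor(zero$table$s_dx, zero$table$expected_min_csa_pct,
                           method = "spearman")), 0.07)

  expect_error(cohort_spec(coupling = 0.99, nuisance_sd = 1),
               "attainable")
  expect_error(cohort_spec(n = 3), "n >= 4")
})

test_that("a minimal cohort runs end-to-end with all invariants", {
  res <- run_phantom_cohort(cohort_spec(n = 4, coupling = 0.5, seed = 21),
                            stages = c("qc", "register", "condyles",
                                       "symphysis", "airway_volumes",
                                       "airway_csa"))
  expect_equal(nrow(res$records), 4L)
  expect_equal(res$n_in, nrow(res$records) + nrow(res$exclusions))
  expect_true(all(res$records$qc_ratio > 0.99 & res$records$qc_ratio < 1.01))
  # measured setbacks match the generator truth
  expect_equal(res$records$S_dX, res$truth_table$s_dx, tolerance = 0.05)
  expect_equal(res$records$min_csa_hypo_pct,
               res$truth_table$expected_min_csa_pct, tolerance = 0.02)
})

test_that("written phantom cases are standard pipeline inputs", {
  dir <- withr::local_tempdir()
  tru <- phantom_truth(symphysis_shift = c(-6, 1), segments = 48,
                       ring_mm = 2.5, subdivisions = 2, arch_segments = 12)
  case <- write_phantom_case(tru, dir, id = "PX")
  expect_true(all(file.exists(unlist(case[c("pre_skull", "post_skull",
                                            "pre_airway", "post_airway")]))))
  rec <- run_patient(case, stages = c("qc", "symphysis", "airway_csa"))
  expect_equal(rec$S_dX, -6, tolerance = 0.05)
  truth_csv <- utils::read.csv(file.path(dir, "PX_truth.csv"))
  expect_equal(truth_csv$s_dx, -6)
})
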