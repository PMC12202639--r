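# the seeded generators: determinism, construction guarantees, and the
# statistical structure they are meant to emulate

test_that("gen_pressure_map is deterministic and peaks where constructed", {
  sc <- cushion_scenario(seed = 42, noise_sd = 0)
  pm <- gen_pressure_map(sc)
  peak_val <- max(pm$grid)
  at_peaks <- pm$grid[sc$peak_centers]
  expect_equal(max(at_peaks), peak_val)

  pm2 <- gen_pressure_map(cushion_scenario(seed = 42, noise_sd = 0))
  expect_identical(pm$grid, pm2$grid)
  a <- gen_pressure_map(cushion_scenario(seed = 1))
  b <- gen_pressure_map(cushion_scenario(seed = 1))
  d <- gen_pressure_map(cushion_scenario(seed = 2))
  expect_identical(a$grid, b$grid)
  expect_false(identical(a$grid, d$grid))

  expect_error(pressure_scenario("cushion", nrow = 10, ncol = 10,
                                 peak_centers = rbind(c(12, 5)),
                                 peak_amplitudes = 5, ellipse_center = c(5, 5),
                                 ellipse_semi = c(4, 4), seed = 1),
               "outside")
})

test_that("ischial peaks dominate the thigh region in 100 seeded draws", {
  for (s in 1:100) {
    pm <- gen_pressure_map(cushion_scenario(seed = s))
    parts <- partition_cushion(pm, split_row = 24)
    hip_max <- compute_metrics(pm, parts$hip)$p_max
    leg_mean <- compute_metrics(pm, parts$legs)$p_ave
    expect_gt(hip_max, leg_mean)
  }
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_pressure_map(cushion_scenario(seed = 3)))
  invisible(gen_spine(10, 20, 30, jitter_sd = 0.1, seed = 4))
  expect_identical(.Random.seed, before)
})

test_that("gen_spine realizes the requested angles exactly without jitter", {
  a <- compute_spinal_angles(gen_spine(0, 0, 0))
  expect_equal(unlist(a), c(cc = 0, ttk = 0, ll = 0), tolerance = 1e-9)
  a40 <- compute_spinal_angles(gen_spine(12, 28, 40))
  expect_equal(a40$ll, 40, tolerance = 1e-6)
  expect_error(gen_spine(95, 10, 10), "< 90")
  # all endplates parallel for the straight spine
  s0 <- gen_spine(0, 0, 0)
  dirs <- t(vapply(s0$vertebrae, function(v) {
    d <- v$sup_ant - v$sup_post
    d / sqrt(sum(d^2))
  }, numeric(3)))
  expect_lt(max(apply(dirs, 2L, stats::sd)), 1e-12)
})

test_that("subject deformation fields average to zero at the landmarks", {
  tpl <- template_cloud(150, seed = 2)
  lm <- template_landmarks(tpl, 10)
  gb <- gen_body_clouds(tpl, lm, n_subjects = 4L, deform_amp = 12,
                        rot_amp = 0, noise_sd = 0, seed = 5L)
  # rot_amp = 0: subjects are pure warps, so their mean is the template
  lm_mean <- Reduce(`+`, lapply(gb$landmarks, `[[`, "coords")) / 4
  expect_equal(lm_mean, lm$coords, tolerance = 1e-9)

  same <- gen_body_clouds(tpl, lm, n_subjects = 3L, deform_amp = 0,
                          rot_amp = 0, noise_sd = 0, seed = 6L)
  for (cl in same$clouds)
    expect_equal(cl$points, tpl$points, ignore_attr = TRUE)
})

test_that("gen_foam_test branches match the constitutive model exactly", {
  fp <- foam_params(30, 2, foam_curve(), hu = 0.35, shape = 1.5)
  tst <- gen_foam_test(fp, eps_max = 0.6, n_points = 40)
  i <- seq_len(tst$i_max)
  expect_equal(tst$stress[i], loading_stress(tst$strain[i], foam_curve()))
  j <- (tst$i_max + 1L):length(tst$strain)
  expect_equal(tst$stress[j],
               unloading_stress(tst$strain[j], 0.6, foam_curve(), 0.35, 1.5))
  # hu = 1: both branches coincide as functions of strain
  fp1 <- foam_params(30, 2, foam_curve(), hu = 1, shape = 1)
  t1 <- gen_foam_test(fp1, eps_max = 0.6, n_points = 40)
  expect_equal(rev(t1$stress[j]), t1$stress[i][-40], tolerance = 1e-12)
})

test_that("condition series are seed-deterministic with monotone clean effects", {
  s1 <- gen_condition_series("whole_chair_flip", c(0, 10, 20, 30, 40),
                             internal_noise_sd = 0, seed = 11L)
  s2 <- gen_condition_series("whole_chair_flip", c(0, 10, 20, 30, 40),
                             internal_noise_sd = 0, seed = 11L)
  expect_identical(s1$conditions[[3L]]$cushion$grid,
                   s2$conditions[[3L]]$cushion$grid)
  vert <- vapply(s1$conditions, function(cd) cd$internal$vertebral_max_stress,
                 numeric(1))
  expect_true(all(diff(vert) < 0))          # monotone decreasing, noise-free
  strain <- vapply(s1$conditions, function(cd) cd$internal$disc_max_strain,
                   numeric(1))
  expect_true(all(diff(strain) > 0))
  expect_error(gen_condition_series("whole_chair_flip", c(0, 10)), ">= 3")
})

test_that("a U-shaped effect concords with a U-shaped surface series", {
  angles <- c(0, 10, 20, 30, 40)
  u_model <- list(disc_max_stress = function(a) 1 + 0.005 * (a - 10)^2)
  s <- gen_condition_series("whole_chair_flip", angles, effect_model = u_model,
                            internal_noise_sd = 0, seed = 21L)
  disc <- vapply(s$conditions, function(cd) cd$internal$disc_max_stress,
                 numeric(1))
  surrogate <- 1 + 0.1 * (angles - 10)^2    # any U-shape with the same ranks
  expect_equal(trend_similarity(surrogate, disc), 1)
})

test_that("generated objects satisfy their type invariants under fuzzing", {
  for (s in 1:50) {
    pm <- gen_pressure_map(backrest_scenario(seed = s))
    expect_true(all(pm$grid >= 0) && all(is.finite(pm$grid)))
    tst <- gen_foam_test(foam_params(30, 2, foam_curve(), 0.5, 1),
                         eps_max = 0.5, n_points = 10,
                         noise_sd = 0.003, seed = s)
    expect_s3_class(tst, "uniaxial_test")   # constructor re-validates path
  }
  for (s in 1:20)
    expect_s3_class(gen_spine(10, 20, 30, jitter_sd = 0.3, seed = s),
                    "spine_landmarks")
})
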