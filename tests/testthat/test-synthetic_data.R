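zero_noise_config <- function(...) {
  sim_config(mandible_trans_sd = c(0, 0, 0), mandible_rot_sd = c(0, 0, 0),
             splint_trans_sd = c(0, 0, 0), splint_rot_sd = c(0, 0, 0),
             deformation_sd = list(skull = c(0, 0, 0), maxilla = c(0, 0, 0),
                                   mandible = c(0, 0, 0)), ...)
}

test_that("template triads are valid, well separated and anatomically ordered", {
  tpl <- default_template()
  expect_named(tpl, c("skull", "maxilla", "mandible"))
  for (tr in tpl) {
    expect_s3_class(tr, "fiducial_triad")
    expect_true(all(inter_point_distances(tr) > 20))
    b <- barycenter(tr)
    # barycenter lies inside the triangle's bounding box
    expect_true(all(b >= apply(tr$points, 2, min) - 1e-9))
    expect_true(all(b <= apply(tr$points, 2, max) + 1e-9))
  }
  # supero-inferior ordering: skull above maxilla above mandible
  expect_gt(barycenter(tpl$skull)[3], barycenter(tpl$maxilla)[3])
  expect_gt(barycenter(tpl$maxilla)[3], barycenter(tpl$mandible)[3])
})

test_that("the planned transform advances 5 mm and tilts for asymmetric impaction", {
  tf <- planned_maxillary_transform()
  # fitted to pure displacement prescriptions: advancement dominates y
  tpl <- default_template()
  moved <- sweep(tpl$maxilla$points %*% t(tf$R), 2, tf$t, "+")
  disp <- colMeans(moved) - colMeans(tpl$maxilla$points)
  expect_equal(unname(disp[2]), 5, tolerance = 0.5)
  # left side goes up, right side goes down (asymmetric vertical plan)
  dz <- (moved - tpl$maxilla$points)[, 3]
  expect_gt(dz[3], dz[2])  # left molar screw vs right molar screw
  expect_equal(det(tf$R), 1, tolerance = 1e-12)
})

test_that("a noise-free study recovers zero error everywhere", {
  sim <- simulate_study(zero_noise_config(n_heads = 3), seed = 5)
  rep <- run_analysis(sim)
  expect_lt(max(rep$overall_rmsd$rmsd), 1e-9)
  expect_lt(max(abs(as.matrix(rep$splint_series[comp_cols]))), 1e-9)
  expect_lt(max(rep$ipd_rmsd$ipd_rmsd), 1e-9)
})

test_that("with zero deformation noise the pipeline recovers the ground-truth transforms", {
  cfg <- sim_config(n_heads = 4,
                    deformation_sd = list(skull = c(0, 0, 0),
                                          maxilla = c(0, 0, 0),
                                          mandible = c(0, 0, 0)))
  sim <- simulate_study(cfg, seed = 17)
  for (h in names(sim$triads)) {
    gt <- sim$ground_truth[[h]]
    pd_md <- pose_difference(sim$triads[[h]]$mandible$planned,
                             sim$triads[[h]]$mandible$postop)
    expect_equal(unname(pd_md$translation$components), gt$mandible$t,
                 tolerance = 1e-9)
    expect_equal(c(pd_md$rotation$pitch, pd_md$rotation$roll,
                   pd_md$rotation$yaw),
                 c(gt$mandible$pitch, gt$mandible$roll, gt$mandible$yaw),
                 tolerance = 1e-9)

    pd_mx <- pose_difference(sim$triads[[h]]$maxilla$planned,
                             sim$triads[[h]]$maxilla$postop)
    expect_equal(unname(pd_mx$translation$components), gt$maxilla$t,
                 tolerance = 1e-9)
    expect_equal(pd_mx$rotation_estimate$R, gt$maxilla$R, tolerance = 1e-9)

    # splint translation components recovered exactly by subtraction
    se_t <- pd_mx$translation$components - pd_md$translation$components
    expect_equal(unname(se_t), gt$splint$t, tolerance = 1e-9)

    # skull receives no transform: its pose difference is identically zero
    pd_sk <- pose_difference(sim$triads[[h]]$skull$planned,
                             sim$triads[[h]]$skull$postop)
    expect_lt(pd_sk$translation$magnitude, 1e-9)
    expect_lt(abs(pd_sk$rotation$pitch), 1e-9)
  }
})

test_that("simulation is bit-reproducible for a given seed", {
  s1 <- simulate_study(sim_config(n_heads = 3), seed = 99)
  s2 <- simulate_study(sim_config(n_heads = 3), seed = 99)
  expect_identical(s1$landmarks, s2$landmarks)

  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  expect_identical(readLines(file.path(d1, "landmarks.csv")),
                   readLines(file.path(d2, "landmarks.csv")))
  expect_identical(readLines(file.path(d1, "ground_truth.json")),
                   readLines(file.path(d2, "ground_truth.json")))

  s3 <- simulate_study(sim_config(n_heads = 3), seed = 100)
  expect_false(identical(s1$landmarks, s3$landmarks))
})

test_that("mean per-axis RMSD of mandibular error matches the chi expectation", {
  # with unit translation SDs, no splint error and no deformation noise,
  # each axis RMSD is ||z||/sqrt(10) for z ~ N(0, I_10), whose mean is
  # sqrt(2/10) * Gamma(11/2) / Gamma(10/2)
  cfg <- sim_config(n_heads = 10,
                    mandible_trans_sd = c(1, 1, 1),
                    mandible_rot_sd = c(0, 0, 0),
                    splint_trans_sd = c(0, 0, 0), splint_rot_sd = c(0, 0, 0),
                    deformation_sd = list(skull = c(0, 0, 0),
                                          maxilla = c(0, 0, 0),
                                          mandible = c(0, 0, 0)))
  set.seed(303)
  n_rep <- 300
  md_rmsd <- matrix(NA_real_, n_rep, 3)
  se_rmsd <- matrix(NA_real_, n_rep, 3)
  for (r in seq_len(n_rep)) {
    sim <- simulate_study(cfg)
    md <- t(vapply(sim$triads, function(tt)
      unname(translation_difference(tt$mandible$planned,
                                    tt$mandible$postop)$components),
      numeric(3)))
    mx <- t(vapply(sim$triads, function(tt)
      unname(translation_difference(tt$maxilla$planned,
                                    tt$maxilla$postop)$components),
      numeric(3)))
    md_rmsd[r, ] <- apply(md, 2, rmsd)
    se_rmsd[r, ] <- apply(mx - md, 2, rmsd)
  }
  expected <- sqrt(2 / 10) * gamma(11 / 2) / gamma(10 / 2)  # 0.97527
  mc_se <- apply(md_rmsd, 2, stats::sd) / sqrt(n_rep)
  for (ax in 1:3) {
    expect_lt(abs(mean(md_rmsd[, ax]) - expected), 3 * mc_se[ax] + 1e-12)
  }
  expect_lt(max(se_rmsd), 1e-9)  # no splint error injected
})

test_that("configuration validation rejects impossible error models", {
  expect_error(sim_config(n_heads = 2), "n_heads")
  expect_error(sim_config(mandible_trans_sd = c(-1, 0, 0)), ">= 0")
  expect_error(sim_config(splint_rot_sd = c(1, 1)), "length 3")
  expect_error(sim_config(deformation_sd = list(skull = c(0, 0, 0))),
               "skull, maxilla and mandible")
})
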