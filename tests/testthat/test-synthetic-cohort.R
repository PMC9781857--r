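test_that("simulation config validates its parameters", {
  expect_error(simulation_config(), class = "fgng_config_error")
  expect_error(simulation_config(seed = 1, n_per_cell = c("AL-Con" = 3)),
               class = "fgng_config_error")
  expect_error(simulation_config(seed = 1, body_water_mean = 0),
               class = "fgng_config_error")
  bad_truth <- default_true_fgng()
  bad_truth$mean[1] <- 1.4
  expect_error(simulation_config(seed = 1, true_fgng = bad_truth),
               class = "fgng_config_error")
  # heavy truncation of a truth cell is flagged, not silently accepted
  wide <- default_true_fgng()
  wide$sd[wide$timepoint == "pre"] <- 0.6
  wide$mean[wide$timepoint == "pre"] <- 0.02
  expect_warning(simulation_config(seed = 1, true_fgng = wide),
                 "truncation")
})

test_that("same seed reproduces identical bundles; design matches cohort sizes", {
  cfg <- simulation_config(seed = 123)
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(simulation_config(seed = 123))
  expect_identical(b1$intensities, b2$intensities)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$bodywater, b2$bodywater)
  b3 <- simulate_cohort(simulation_config(seed = 124))
  expect_false(identical(b1$intensities, b3$intensities))

  counts <- dplyr::count(b1$design, .data$cell)
  expect_identical(setNames(counts$n, counts$cell),
                   c("AL+TBI" = 6L, "AL-Con" = 3L, "CR+TBI" = 5L,
                     "CR-Con" = 6L))
  # every measurement row joins exactly one design animal, truth recorded
  expect_true(all(b1$intensities$animal_id %in% b1$design$animal_id))
  expect_identical(sort(unique(b1$intensities$sample_id)),
                   sort(b1$truth$sample_id))
  expect_identical(nrow(b1$truth), 2L * nrow(b1$design))
})

test_that("noise-free linear simulation is inverted exactly by the pipeline", {
  b <- simulate_cohort(simulation_config(seed = 5, intensity_noise_cv = 0))
  res <- analyze_cohort(b)$results
  chk <- dplyr::left_join(res,
                          b$truth[, c("sample_id", "true_fgng")],
                          by = "sample_id")
  expect_lt(max(abs(chk$fgng - chk$true_fgng)), 1e-10)
})

test_that("estimator bias under default linear settings vanishes at scale", {
  cfg <- simulation_config(
    seed = 21,
    n_per_cell = c("AL-Con" = 500L, "AL+TBI" = 500L,
                   "CR-Con" = 500L, "CR+TBI" = 500L))
  b <- simulate_cohort(cfg)
  res <- analyze_cohort(b)$results
  chk <- dplyr::left_join(res, b$truth[, c("sample_id", "true_fgng")],
                          by = "sample_id")
  bias_pp <- 100 * mean(chk$fgng - chk$true_fgng)
  expect_lt(abs(bias_pp), 0.5)
})

test_that("binomial-mode cohorts show exactly the model-predicted bias", {
  cfg <- simulation_config(seed = 31, intensity_noise_cv = 0,
                           body_water_sd = 0,
                           incorporation_mode = "binomial")
  b <- simulate_cohort(cfg)
  res <- analyze_cohort(b)$results
  chk <- dplyr::left_join(res, b$truth[, c("sample_id", "true_fgng",
                                           "true_body_water")],
                          by = "sample_id")
  fr <- fragment_model()
  predicted <- purrr::map2_dbl(chk$true_body_water, chk$true_fgng,
                               function(pw, f) {
                                 d <- label_distribution(pw, f, fr,
                                                         mode = "binomial")
                                 (d[2] / d[1]) / 6 / pw
                               })
  expect_equal(chk$fgng, pmin(predicted, 1), tolerance = 1e-9)
})

test_that("replicate cohorts converge on the configured truth", {
  seeds <- 1000 + seq_len(120)
  cr_post <- vapply(seeds, function(s) {
    b <- simulate_cohort(simulation_config(seed = s))
    res <- analyze_cohort(b)$results
    mean(res$fgng[res$feeding == "CR" & res$timepoint == "post"])
  }, numeric(1))
  mc_se <- sd(cr_post) / sqrt(length(cr_post))
  truth <- (6 * 0.7983 + 5 * 0.7910) / 11
  expect_lt(abs(mean(cr_post) - truth), 2 * mc_se)
})

test_that("trajectories reproduce the published skeleton when noise is off", {
  cfg <- simulation_config(seed = 9, trajectory_noise = 0)
  tr <- simulate_trajectories(cfg)
  al_con <- dplyr::filter(tr, .data$cell == "AL-Con")
  expect_equal(unique(al_con$weight_change_g), 45.0, tolerance = 1e-9)
  expect_equal(al_con$weight_g[al_con$timepoint == "pre"],
               rep(249.3, 3), tolerance = 1e-9)
  # CR final ration: half of the pre intake rounded up to the half gram
  cr <- dplyr::filter(tr, .data$feeding == "CR", .data$timepoint == "post13d")
  expect_equal(cr$food_g[cr$cell == "CR-Con"], rep(12.5, 6))   # 25.0 -> 12.5
  expect_equal(cr$food_g[cr$cell == "CR+TBI"], rep(11.0, 5))   # 21.9 -> 22 -> 11

  tr2 <- simulate_trajectories(simulation_config(seed = 9,
                                                 trajectory_noise = 0))
  expect_identical(tr, tr2)
})
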