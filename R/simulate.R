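#' Default true group parameters for the simulated cohort
#'
#' Per feeding x injury cell and timepoint: the true mean and between-animal
#' SD of fractional gluconeogenesis (as fractions). The post-intervention
#' values use the published per-cell summaries directly as SDs; the
#' pre-intervention dispersions are published as standard errors of pooled
#' feeding groups and are converted to between-animal SDs (SE * sqrt(n),
#' n = 9 AL / 11 CR) — the conversion each printed significance test is
#' consistent with (see the methods vignette). Pre-intervention truth is set
#' at the feeding-group level because per-cell pre values are not resolved.
#'
#' @return A tibble with columns `feeding`, `injury`, `timepoint`, `mean`,
#'   `sd` (fractions of 1).
#' @export
default_true_fgng <- function() {
  bind_rows(
    expand_grid(feeding = "AL", injury = c("Con", "TBI"), timepoint = "pre",
                mean = 0.3540, sd = 0.0110 * sqrt(9)),
    expand_grid(feeding = "CR", injury = c("Con", "TBI"), timepoint = "pre",
                mean = 0.3662, sd = 0.0171 * sqrt(11)),
    tibble(feeding = c("AL", "AL", "CR", "CR"),
           injury = c("Con", "TBI", "Con", "TBI"),
           timepoint = "post",
           mean = c(0.6264, 0.5985, 0.7983, 0.7910),
           sd = c(0.0633, 0.0501, 0.0443, 0.0452))
  )
}

#' Configuration for the synthetic rat cohort
#'
#' Bundles every knob of the simulated study into one validated object. The
#' defaults are the study conditions of the 2x2 feeding (AL ad libitum / CR
#' 50% caloric restriction) by injury (sham Con / TBI) design: cell sizes
#' 3/6/6/5, drinking water at 6% D2O with body water settling slightly
#' below it, and true fGNG distributions taken from the published group
#' summaries (see [default_true_fgng()]).
#'
#' @param seed Integer RNG seed; mandatory for reproducibility.
#' @param n_per_cell Named integer vector of animals per cell; names
#'   `AL-Con`, `AL+TBI`, `CR-Con`, `CR+TBI`. Default `c(3, 6, 6, 5)`.
#' @param true_fgng Tibble like [default_true_fgng()]: per cell x timepoint
#'   `mean` and between-animal `sd` of true fGNG (fractions).
#' @param body_water_mean,body_water_sd Between-animal distribution of true
#'   body-water D2O enrichment (fractions). Default mean 0.055 — a little
#'   below the 6% drinking water because food and metabolic water are
#'   unlabeled — and SD 0.003.
#' @param intensity_noise_cv Coefficient of variation of the multiplicative
#'   lognormal noise applied independently to each SIM channel of each
#'   injection. Default 0.02, a routine GC-MS repeatability level.
#' @param n_injections Repeated injections per sample (default 3).
#' @param incorporation_mode `"linear"` (default; first-order labeling, so
#'   the estimator is exact) or `"binomial"` (exact site labeling).
#' @param background_composition Elemental composition for natural-abundance
#'   background in the simulated spectra; default empty (no background),
#'   matching the raw-ratio convention.
#' @param base_intensity Arbitrary M-channel ion count scale (default 1e6).
#' @param dilution_factor Sample dilution before the water-isotope analyzer
#'   (default 300); standards are carried through the same dilution.
#' @param curve_slope,curve_intercept The simulated analyzer's response
#'   line on diluted standards, in body-water-fraction units.
#' @param trajectory_noise Multiplier on the between-animal SDs of the
#'   optional weight/food trajectories (0 = deterministic cell means).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_per_cell = c("AL-Con" = 3L, "AL+TBI" = 6L,
                                             "CR-Con" = 6L, "CR+TBI" = 5L),
                              true_fgng = default_true_fgng(),
                              body_water_mean = 0.055,
                              body_water_sd = 0.003,
                              intensity_noise_cv = 0.02,
                              n_injections = 3L,
                              incorporation_mode = c("linear", "binomial"),
                              background_composition = NULL,
                              base_intensity = 1e6,
                              dilution_factor = 300,
                              curve_slope = 0.995,
                              curve_intercept = 2e-4,
                              trajectory_noise = 1) {
  if (missing(seed) || !is.finite(seed)) {
    abort("A finite integer `seed` is mandatory.", class = "fgng_config_error")
  }
  incorporation_mode <- match.arg(incorporation_mode)
  cells <- c("AL-Con", "AL+TBI", "CR-Con", "CR+TBI")
  if (!all(cells %in% names(n_per_cell))) {
    abort(paste0("`n_per_cell` must name all four cells: ",
                 paste(cells, collapse = ", ")),
          class = "fgng_config_error")
  }
  n_per_cell <- as.integer(n_per_cell[cells])
  names(n_per_cell) <- cells
  if (any(n_per_cell < 1L)) {
    abort("Each cell needs at least one animal.", class = "fgng_config_error")
  }
  true_fgng <- as_tibble(true_fgng)
  stopifnot(all(c("feeding", "injury", "timepoint", "mean", "sd") %in%
                  names(true_fgng)))
  if (any(true_fgng$mean < 0 | true_fgng$mean > 1) ||
      any(true_fgng$sd < 0)) {
    abort("True fGNG means must be fractions in [0, 1] and SDs >= 0.",
          class = "fgng_config_error")
  }
  if (body_water_mean <= 0 || body_water_mean > 1 || body_water_sd < 0) {
    abort("Body-water parameters out of range.", class = "fgng_config_error")
  }
  if (intensity_noise_cv < 0 || n_injections < 1) {
    abort("Noise CV must be >= 0 and n_injections >= 1.",
          class = "fgng_config_error")
  }
  # warn when truncation to [0, 1] would reshape a truth distribution badly
  trunc_mass <- pnorm(0, true_fgng$mean, pmax(true_fgng$sd, 1e-12)) +
    pnorm(1, true_fgng$mean, pmax(true_fgng$sd, 1e-12), lower.tail = FALSE)
  if (any(true_fgng$sd > 0 & trunc_mass > 0.5)) {
    warn("A true-fGNG cell places > 50% of its normal mass outside [0, 1]; truncation will distort it.")
  }
  structure(
    list(seed = as.integer(seed), n_per_cell = n_per_cell,
         true_fgng = true_fgng, body_water_mean = body_water_mean,
         body_water_sd = body_water_sd,
         intensity_noise_cv = intensity_noise_cv,
         n_injections = as.integer(n_injections),
         incorporation_mode = incorporation_mode,
         background_composition = background_composition,
         base_intensity = base_intensity,
         dilution_factor = dilution_factor,
         curve_slope = curve_slope, curve_intercept = curve_intercept,
         trajectory_noise = trajectory_noise),
    class = "simulation_config"
  )
}

# Truncated-normal draws by inverse-CDF (no rejection loop; exact under a
# fixed RNG stream).
rtruncnorm01 <- function(n, mean, sd, lower = 0, upper = 1) {
  if (all(sd == 0)) return(rep(mean, length.out = n))
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

# Lognormal multiplicative noise with unit mean and the given CV.
rln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a complete raw-input bundle for the labeled-water study
#'
#' Generates everything the pipeline ingests, with recorded truth: a design
#' table (animal, feeding, injury), per-animal per-timepoint true fGNG and
#' body-water enrichment, per-injection SIM intensity pairs at m/z 169/170,
#' body-water analyzer readings, and the D2O standard curve the readings are
#' calibrated against. Deterministic given the seed (Mersenne-Twister,
#' inversion normals).
#'
#' For each animal and timepoint the generator draws true fGNG from the
#' cell's truncated normal and true body water from its truncated normal,
#' builds the fragment isotopologue distribution in the configured
#' incorporation mode (plus natural-abundance background if a composition is
#' configured), scales it by the base intensity, and applies independent
#' lognormal noise per channel and injection. Body-water readings pass
#' through the simulated standard curve noiselessly — the analyzer's
#' repeatability is far tighter than the biological spread being modeled.
#'
#' @param config A [simulation_config()].
#' @return An object of class `cohort_bundle`: a list of tibbles `design`,
#'   `truth`, `intensities`, `bodywater`, `standard_curve`, plus the
#'   `config`.
#' @examples
#' bundle <- simulate_cohort(simulation_config(seed = 1))
#' head(bundle$intensities)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  fragment <- fragment_model(composition = config$background_composition)

  design <- imap(config$n_per_cell, function(n, cell) {
    feeding <- sub("[-+].*$", "", cell)
    injury <- sub("^.*[-+]", "", cell)
    injury <- ifelse(injury == "Con", "Con", "TBI")
    tibble(cell = cell, feeding = feeding, injury = injury,
           idx = seq_len(n))
  }) |>
    list_rbind() |>
    mutate(animal_id = sprintf("%s_%d", gsub("[^A-Za-z]", "", .data$cell),
                               .data$idx)) |>
    select("animal_id", "feeding", "injury", "cell")

  truth <- expand_grid(animal_id = design$animal_id,
                       timepoint = c("pre", "post")) |>
    left_join(design, by = "animal_id") |>
    left_join(config$true_fgng, by = c("feeding", "injury", "timepoint"))
  truth$true_fgng <- rtruncnorm01(nrow(truth), truth$mean, truth$sd)
  truth$true_body_water <- rtruncnorm01(nrow(truth), config$body_water_mean,
                                        config$body_water_sd)
  truth <- truth |>
    mutate(sample_id = paste(.data$animal_id, .data$timepoint, sep = "_")) |>
    select("sample_id", "animal_id", "timepoint", "feeding", "injury",
           "cell", "true_fgng", "true_body_water")

  dists <- bind_cols(
    sample_id = truth$sample_id,
    sample_mass_probs(truth$true_body_water, truth$true_fgng,
                      fragment, config$incorporation_mode))
  intensities <- expand_grid(sample_id = truth$sample_id,
                             injection = seq_len(config$n_injections)) |>
    left_join(select(truth, "sample_id", "animal_id", "timepoint"),
              by = "sample_id") |>
    left_join(dists, by = "sample_id")
  k <- nrow(intensities)
  intensities <- intensities |>
    mutate(
      intensity_m = config$base_intensity * .data$p0 *
        rln_noise(k, config$intensity_noise_cv),
      intensity_m1 = config$base_intensity * .data$p1 *
        rln_noise(k, config$intensity_noise_cv)
    ) |>
    select("sample_id", "animal_id", "timepoint", "injection",
           "intensity_m", "intensity_m1")

  standard_curve <- tibble(
    known_fraction = c(0, 0.01, 0.02, 0.04, 0.06, 0.08, 0.10)
  ) |>
    mutate(reading = config$curve_slope * .data$known_fraction +
             config$curve_intercept)
  bodywater <- truth |>
    mutate(reading = config$curve_slope * .data$true_body_water +
             config$curve_intercept) |>
    select("sample_id", "reading")

  structure(list(design = design, truth = truth, intensities = intensities,
                 bodywater = bodywater, standard_curve = standard_curve,
                 config = config),
            class = "cohort_bundle")
}

# For each sample: the M and M+1 probabilities of its isotopologue
# distribution under the configured incorporation mode (+ background).
sample_mass_probs <- function(p_water, fgng_true, fragment, mode) {
  bg <- background_distribution(fragment)
  pair <- function(pw, f) {
    d <- label_distribution(pw, f, fragment, mode = mode)
    if (length(bg) > 1L) d <- convolve_background(d, fragment)
    c(d[1], d[2])
  }
  m <- vapply(seq_along(p_water),
              function(i) pair(p_water[i], fgng_true[i]), numeric(2))
  tibble(p0 = m[1, ], p1 = m[2, ])
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle>", nrow(x$design), "animals,",
      nrow(x$intensities), "injections,",
      "seed", x$config$seed, "\n")
  invisible(x)
}

#' Simulate optional weight and food-intake trajectories
#'
#' Per-animal body-weight and food-consumption series over the three
#' reported timepoints (pre-intervention, 24 h post, 13 days post). The
#' deterministic skeleton is the published per-cell means; per-animal
#' Gaussian noise uses the published per-cell SDs scaled by
#' `trajectory_noise` (0 gives exact cell means). Food allotment for the
#' calorically restricted cells at the final timepoint follows the study's
#' rationing rule: each animal's pre-intervention daily intake rounded up to
#' the nearest half gram, then halved.
#'
#' @param config A [simulation_config()].
#' @return A tibble with columns `animal_id`, `feeding`, `injury`, `cell`,
#'   `timepoint` (`pre`, `post24h`, `post13d`), `weight_g`, `food_g`, and
#'   `weight_change_g` (final minus pre, repeated per animal).
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L, kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  cells <- c("AL-Con", "AL+TBI", "CR-Con", "CR+TBI")
  weight_mean <- rbind("AL-Con" = c(249.3, 248.7, 294.3),
                       "AL+TBI" = c(252.2, 241.2, 285.3),
                       "CR-Con" = c(292.16, 291.5, 278.3),
                       "CR+TBI" = c(244.8, 233.0, 216.6))
  weight_sd <- rbind("AL-Con" = c(2.1, 0.6, 6.7),
                     "AL+TBI" = c(15.8, 15.5, 16.1),
                     "CR-Con" = c(14.8, 15.3, 10.6),
                     "CR+TBI" = c(13.9, 12.1, 15.8))
  food_mean <- rbind("AL-Con" = c(22.5, 18.0, 21.1),
                     "AL+TBI" = c(22.7, 12.3, 21.0),
                     "CR-Con" = c(25.0, 12.8, NA),
                     "CR+TBI" = c(21.9, 11.0, NA))
  food_sd <- rbind("AL-Con" = c(0.8, 2.6, 1.4),
                   "AL+TBI" = c(1.2, 4.5, 1.5),
                   "CR-Con" = c(1.2, 0.4, 0),
                   "CR+TBI" = c(1.9, 1.0, 0))
  tps <- c("pre", "post24h", "post13d")
  out <- imap(config$n_per_cell, function(n, cell) {
    feeding <- sub("[-+].*$", "", cell)
    injury <- sub("^.*[-+]", "", cell)
    k <- config$trajectory_noise
    rows <- map(seq_len(n), function(i) {
      w <- weight_mean[cell, ] + rnorm(3, 0, k * weight_sd[cell, ])
      f <- food_mean[cell, ] + rnorm(3, 0, k * food_sd[cell, ])
      if (feeding == "CR") {
        # half of the pre-intervention intake rounded up to nearest 0.5 g
        f[3] <- ceiling(f[1] * 2) / 2 / 2
      }
      tibble(animal_id = sprintf("%s_%d", gsub("[^A-Za-z]", "", cell), i),
             feeding = feeding, injury = injury, cell = cell,
             timepoint = tps, weight_g = w, food_g = f,
             weight_change_g = w[3] - w[1])
    })
    list_rbind(rows)
  }) |>
    list_rbind()
  out$timepoint <- factor(out$timepoint, levels = tps)
  out
}
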