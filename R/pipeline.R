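#' Write / read a cohort bundle as plain CSV tables
#'
#' A cohort bundle on disk is a directory of UTF-8 CSVs with headers:
#' `design.csv`, `sim_intensities.csv`, `bodywater_readings.csv`,
#' `standard_curve.csv` and (for simulated data) `truth.csv`. All
#' enrichments are fractions; percent formatting belongs to the report
#' layer only.
#'
#' @param bundle A `cohort_bundle` (from [simulate_cohort()] or
#'   [read_cohort_bundle()]).
#' @param dir Directory path.
#' @return `write_cohort_bundle()` returns `dir` invisibly;
#'   `read_cohort_bundle()` returns a `cohort_bundle`.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(bundle$design, file.path(dir, "design.csv"))
  readr::write_csv(bundle$intensities, file.path(dir, "sim_intensities.csv"))
  readr::write_csv(bundle$bodywater, file.path(dir, "bodywater_readings.csv"))
  readr::write_csv(bundle$standard_curve, file.path(dir, "standard_curve.csv"))
  if (!is.null(bundle$truth)) {
    readr::write_csv(bundle$truth, file.path(dir, "truth.csv"))
  }
  invisible(dir)
}

#' @rdname write_cohort_bundle
#' @export
read_cohort_bundle <- function(dir) {
  need <- c("design.csv", "sim_intensities.csv", "bodywater_readings.csv",
            "standard_curve.csv")
  paths <- file.path(dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("Missing input file(s) in ", dir, ": ",
                 paste(missing, collapse = ", ")),
          class = "fgng_io_error")
  }
  rd <- function(f) readr::read_csv(file.path(dir, f), show_col_types = FALSE)
  truth_path <- file.path(dir, "truth.csv")
  structure(
    list(design = rd("design.csv"),
         truth = if (file.exists(truth_path)) rd("truth.csv") else NULL,
         intensities = rd("sim_intensities.csv"),
         bodywater = rd("bodywater_readings.csv"),
         standard_curve = rd("standard_curve.csv"),
         config = NULL),
    class = "cohort_bundle")
}

#' Validate a cohort bundle before analysis
#'
#' Schema and integrity checks on the input tables: required columns,
#' duplicate identifiers, orphan rows that fail to join the design table,
#' and out-of-range values (non-positive M intensities, negative M+1,
#' readings outside the standard-curve span by more than an order of
#' magnitude are left to calibration). Returns every problem found rather
#' than stopping at the first.
#'
#' @param bundle A `cohort_bundle` (or a directory path, read first).
#' @return A tibble with columns `table`, `issue`, `detail`; zero rows means
#'   the bundle is analyzable.
#' @examples
#' b <- simulate_cohort(simulation_config(seed = 1))
#' validate_inputs(b)
#' @export
validate_inputs <- function(bundle) {
  if (is.character(bundle)) bundle <- read_cohort_bundle(bundle)
  stopifnot(inherits(bundle, "cohort_bundle"))
  issues <- list()
  note <- function(table, issue, detail) {
    issues[[length(issues) + 1L]] <<- tibble(table = table, issue = issue,
                                             detail = detail)
  }
  need_cols <- list(
    design = c("animal_id", "feeding", "injury"),
    intensities = c("sample_id", "animal_id", "timepoint",
                    "intensity_m", "intensity_m1"),
    bodywater = c("sample_id", "reading"),
    standard_curve = c("known_fraction", "reading"))
  for (tb in names(need_cols)) {
    miss <- setdiff(need_cols[[tb]], names(bundle[[tb]]))
    if (length(miss) > 0) {
      note(tb, "missing_column", paste(miss, collapse = ", "))
    }
  }
  if (nrow(dplyr::bind_rows(issues)) > 0) {
    return(list_rbind(issues))  # structural failures mask the value checks
  }
  dup_animal <- bundle$design$animal_id[duplicated(bundle$design$animal_id)]
  if (length(dup_animal) > 0) {
    note("design", "duplicate_id", paste(unique(dup_animal), collapse = ", "))
  }
  dup_bw <- bundle$bodywater$sample_id[duplicated(bundle$bodywater$sample_id)]
  if (length(dup_bw) > 0) {
    note("bodywater", "duplicate_id", paste(unique(dup_bw), collapse = ", "))
  }
  orphan <- setdiff(bundle$intensities$animal_id, bundle$design$animal_id)
  if (length(orphan) > 0) {
    note("intensities", "orphan_animal", paste(orphan, collapse = ", "))
  }
  no_bw <- setdiff(unique(bundle$intensities$sample_id),
                   bundle$bodywater$sample_id)
  if (length(no_bw) > 0) {
    note("intensities", "no_bodywater_reading", paste(no_bw, collapse = ", "))
  }
  bad_m <- which(!is.finite(bundle$intensities$intensity_m) |
                   bundle$intensities$intensity_m <= 0)
  if (length(bad_m) > 0) {
    note("intensities", "nonpositive_intensity_m",
         paste0("row(s) ", paste(bad_m, collapse = ", ")))
  }
  bad_m1 <- which(!is.finite(bundle$intensities$intensity_m1) |
                    bundle$intensities$intensity_m1 < 0)
  if (length(bad_m1) > 0) {
    note("intensities", "negative_intensity_m1",
         paste0("row(s) ", paste(bad_m1, collapse = ", ")))
  }
  if (length(unique(bundle$standard_curve$known_fraction)) < 2) {
    note("standard_curve", "degenerate_curve",
         "fewer than 2 distinct known fractions")
  }
  if (length(issues) == 0) {
    return(tibble(table = character(), issue = character(),
                  detail = character()))
  }
  list_rbind(issues)
}

#' Run the full labeled-water analysis on a cohort bundle
#'
#' The end-to-end sequence: fit the standard curve, calibrate body-water
#' readings into enrichment fractions, ratio the SIM intensity pairs per
#' injection and average per sample, convert to fragment enrichment, divide
#' by body-water enrichment to get per-animal fGNG, classify dietary
#' adequacy, then run the group statistics — pre- and post-intervention
#' AL-vs-CR t-tests, a post Con-vs-TBI t-test, the Type III two-way ANOVA
#' and Tukey-Kramer post hoc on the post-intervention measurements.
#'
#' @param bundle A `cohort_bundle` or a directory path of input CSVs.
#' @param fragment A [fragment_model()].
#' @param background_ratio M+1/M background ratio subtracted before the
#'   site-count division (default 0: raw-ratio convention).
#' @param ss_type ANOVA sum-of-squares type, 3 (default) or 1.
#' @param t_test `"student"` (pooled, default) or `"welch"`.
#' @param dilution_factor,curve_includes_dilution Passed to
#'   [enrichment_from_reading()].
#' @return An object of class `fgng_report`: list with tibbles `results`
#'   (per animal x timepoint), `group_summary` (per cell x timepoint),
#'   `anova` (tidied post-intervention table), `t_tests`, `tukey`, and the
#'   `options` used.
#' @examples
#' rep <- analyze_cohort(simulate_cohort(simulation_config(seed = 1)))
#' rep$group_summary
#' @export
analyze_cohort <- function(bundle, fragment = fragment_model(),
                           background_ratio = 0, ss_type = 3,
                           t_test = c("student", "welch"),
                           dilution_factor = 300,
                           curve_includes_dilution = TRUE) {
  t_test <- match.arg(t_test)
  if (is.character(bundle)) bundle <- read_cohort_bundle(bundle)
  stopifnot(inherits(bundle, "cohort_bundle"))
  problems <- validate_inputs(bundle)
  if (nrow(problems) > 0) {
    abort(paste0("Input validation failed:\n",
                 paste(sprintf("  [%s] %s: %s", problems$table,
                               problems$issue, problems$detail),
                       collapse = "\n")),
          class = "fgng_validation_error")
  }
  curve <- fit_standard_curve(bundle$standard_curve)
  bw <- enrichment_from_reading(curve, bundle$bodywater,
                                dilution_factor = dilution_factor,
                                curve_includes_dilution = curve_includes_dilution)
  enr <- fragment_enrichment(bundle$intensities, fragment = fragment,
                             background_ratio = background_ratio)
  res <- compute_fgng(enr, bw)
  meta <- distinct(bundle$intensities, .data$sample_id, .data$animal_id,
                   .data$timepoint) |>
    left_join(bundle$design, by = "animal_id")
  results <- left_join(res, meta, by = "sample_id") |>
    mutate(timepoint = factor(.data$timepoint, levels = c("pre", "post"))) |>
    select("sample_id", "animal_id", "feeding", "injury", "timepoint",
           "fragment_enrichment", "body_water_enrichment", "fgng",
           "feeding_state", "overfed_flag", "qc_flags") |>
    arrange(.data$timepoint, .data$feeding, .data$injury, .data$animal_id)

  group_summary <- results |>
    group_by(.data$timepoint, .data$feeding, .data$injury) |>
    summarise(n = dplyr::n(), mean_fgng = mean(.data$fgng),
              sd_fgng = sd(.data$fgng), .groups = "drop")

  post <- filter(results, .data$timepoint == "post")
  pre <- filter(results, .data$timepoint == "pre")
  var_equal <- t_test == "student"
  t_tests <- bind_rows(
    mutate(independent_t_test(pre$fgng[pre$feeding == "AL"],
                              pre$fgng[pre$feeding == "CR"], var_equal),
           comparison = "pre: AL vs CR", .before = 1),
    mutate(independent_t_test(post$fgng[post$feeding == "AL"],
                              post$fgng[post$feeding == "CR"], var_equal),
           comparison = "post: AL vs CR", .before = 1),
    mutate(independent_t_test(post$fgng[post$injury == "Con"],
                              post$fgng[post$injury == "TBI"], var_equal),
           comparison = "post: Con vs TBI", .before = 1))

  anova_post <- two_way_anova(post, response = "fgng", ss_type = ss_type)
  tukey_post <- tukey_hsd(post, response = "fgng")

  structure(
    list(results = results, group_summary = group_summary,
         anova = tidy(anova_post), anova_fit = anova_post,
         t_tests = t_tests, tukey = tukey_post,
         options = list(n_sites = fragment$n_sites,
                        base_mz = fragment$base_mz,
                        composition = fragment$composition,
                        background_ratio = background_ratio,
                        ss_type = ss_type, t_test = t_test,
                        dilution_factor = dilution_factor,
                        curve_includes_dilution = curve_includes_dilution)),
    class = "fgng_report")
}

#' @export
print.fgng_report <- function(x, ...) {
  cat("<fgng_report>\n\nGroup summary (fractions):\n")
  print(as.data.frame(x$group_summary), digits = 4)
  cat("\nPost-intervention two-way ANOVA (Type", x$options$ss_type, "SS):\n")
  print(as.data.frame(x$anova), digits = 4)
  cat("\nt-tests:\n")
  print(as.data.frame(x$t_tests), digits = 4)
  invisible(x)
}

#' Run the pipeline and write its report bundle to disk
#'
#' [analyze_cohort()] plus file output: per-animal results, group summary,
#' ANOVA / t-test / Tukey tables as CSV, and a JSON manifest carrying the
#' option hash, the simulation seed when the bundle records one, and the
#' package version. Outputs contain no timestamps, so re-running on
#' identical inputs reproduces byte-identical files; on any failure,
#' partial outputs in `out_dir` are removed.
#'
#' @inheritParams analyze_cohort
#' @param out_dir Output directory (created if needed).
#' @param ... Passed to [analyze_cohort()].
#' @return The `fgng_report`, invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(bundle, out_dir, ...) {
  if (is.character(bundle)) bundle <- read_cohort_bundle(bundle)
  report <- analyze_cohort(bundle, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path)
    written <<- c(written, path)
  }
  tryCatch({
    emit(report$results, "fgng_results.csv")
    emit(report$group_summary, "group_summary.csv")
    emit(report$anova, "anova.csv")
    emit(report$t_tests, "t_tests.csv")
    emit(report$tukey, "tukey.csv")
    manifest <- list(
      config_hash = rlang::hash(report$options),
      seed = bundle$config$seed,
      software = paste0("fgng ", as.character(packageVersion("fgng"))),
      options = report$options,
      tables = basename(written))
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
    written <- c(written, manifest_path)
  }, error = function(e) {
    unlink(written)
    abort("Pipeline output failed; partial files removed.",
          parent = e, class = "fgng_io_error")
  })
  invisible(report)
}
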