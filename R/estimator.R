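#' Fragment enrichment from SIM intensity pairs
#'
#' The deuterium enrichment of the monitored fragment: the M+1/M intensity
#' ratio (m/z 170 over m/z 169 for glucose penta-acetate), optionally minus
#' an unlabeled-baseline background ratio, divided by the number of
#' exchangeable hydrogen sites (6). Division by the site count converts the
#' per-molecule M+1 excess into an average per-site enrichment comparable to
#' the body-water deuterium fraction.
#'
#' Background subtraction defaults to off (`background_ratio = 0`), the
#' raw-ratio convention; a per-batch baseline from unlabeled samples, or
#' [natural_abundance_m1()] from an assumed composition, can be supplied.
#' Ratios that go negative after subtraction are floored at 0 and QC-flagged.
#'
#' @param measurements Data frame with columns `sample_id`, `intensity_m`
#'   and `intensity_m1` (one row per sample, or per injection — rows sharing
#'   a `sample_id` are ratioed per row and averaged per sample).
#' @param fragment A [fragment_model()].
#' @param background_ratio Non-negative M+1/M ratio subtracted before the
#'   site-count division. Default 0.
#' @return A tibble with one row per `sample_id`: `n_injections`,
#'   `mean_ratio`, `fragment_enrichment`, and `qc_flags` (character,
#'   `""` or `"negative_after_background"`).
#' @examples
#' m <- tibble::tibble(sample_id = "r1", intensity_m = 1000,
#'                     intensity_m1 = 360)
#' fragment_enrichment(m)   # 0.36 / 6 = 0.06
#' @export
fragment_enrichment <- function(measurements, fragment = fragment_model(),
                                background_ratio = 0) {
  stopifnot(inherits(fragment, "fragment_model"))
  measurements <- as_tibble(measurements)
  required <- c("sample_id", "intensity_m", "intensity_m1")
  if (!all(required %in% names(measurements))) {
    abort(paste0("Measurement table needs columns: ",
                 paste(required, collapse = ", ")),
          class = "fgng_validation_error")
  }
  if (!is.finite(background_ratio) || background_ratio < 0) {
    abort("`background_ratio` must be a non-negative fraction.",
          class = "fgng_domain_error")
  }
  bad_m <- !is.finite(measurements$intensity_m) | measurements$intensity_m <= 0
  if (any(bad_m)) {
    abort(paste0("Non-positive M intensity for sample(s): ",
                 paste(unique(measurements$sample_id[bad_m]), collapse = ", ")),
          class = "fgng_measurement_error")
  }
  if (any(!is.finite(measurements$intensity_m1) |
          measurements$intensity_m1 < 0)) {
    abort("M+1 intensities must be non-negative.",
          class = "fgng_measurement_error")
  }
  measurements |>
    mutate(.ratio = .data$intensity_m1 / .data$intensity_m) |>
    group_by(.data$sample_id) |>
    summarise(n_injections = dplyr::n(),
              mean_ratio = mean(.data$.ratio), .groups = "drop") |>
    mutate(
      .excess = .data$mean_ratio - background_ratio,
      # flag whenever background subtraction consumed (or inverted) the signal
      qc_flags = if_else(.data$.excess <= 0 & background_ratio > 0,
                         "negative_after_background", ""),
      fragment_enrichment = pmax(.data$.excess, 0) / fragment$n_sites
    ) |>
    select("sample_id", "n_injections", "mean_ratio",
           "fragment_enrichment", "qc_flags")
}

#' Fractional gluconeogenesis from fragment and body-water enrichment
#'
#' The defining ratio of the heavy-water method: fractional gluconeogenesis
#' is the fragment's per-site deuterium enrichment divided by the body-water
#' deuterium enrichment (the precursor enrichment). A fully gluconeogenic
#' glucose pool labels its exchangeable sites at the body-water level, so
#' the ratio runs from 0 (no new glucose) to 1 (all glucose newly made).
#'
#' Measurement noise can push the ratio slightly past 1: values in
#' `(1, 1.05]` are clamped to 1 and QC-flagged `"superunity"`; values above
#' 1.05 indicate inconsistent inputs and abort. Each result also carries the
#' dietary-adequacy classification from [classify_feeding_state()].
#'
#' @param enrichment A tibble from [fragment_enrichment()] (or any data
#'   frame with `sample_id` and `fragment_enrichment`).
#' @param body_water A tibble from [enrichment_from_reading()] (or any data
#'   frame with `sample_id` and `enrichment`), joined on `sample_id`.
#' @return A tibble with columns `sample_id`, `fragment_enrichment`,
#'   `body_water_enrichment`, `fgng`, `feeding_state`, `overfed_flag`,
#'   `qc_flags`.
#' @examples
#' enr <- tibble::tibble(sample_id = "r1", fragment_enrichment = 0.03,
#'                       qc_flags = "")
#' bw  <- tibble::tibble(sample_id = "r1", enrichment = 0.06)
#' compute_fgng(enr, bw)   # fGNG 0.5
#' @export
compute_fgng <- function(enrichment, body_water) {
  enrichment <- as_tibble(enrichment)
  body_water <- as_tibble(body_water)
  if (!all(c("sample_id", "fragment_enrichment") %in% names(enrichment))) {
    abort("`enrichment` needs columns sample_id and fragment_enrichment.",
          class = "fgng_validation_error")
  }
  if (!all(c("sample_id", "enrichment") %in% names(body_water))) {
    abort("`body_water` needs columns sample_id and enrichment.",
          class = "fgng_validation_error")
  }
  if (!"qc_flags" %in% names(enrichment)) enrichment$qc_flags <- ""
  orphans <- anti_join(enrichment, body_water, by = "sample_id")
  if (nrow(orphans) > 0) {
    abort(paste0("No body-water enrichment for sample(s): ",
                 paste(orphans$sample_id, collapse = ", ")),
          class = "fgng_validation_error")
  }
  res <- inner_join(
    select(enrichment, "sample_id", "fragment_enrichment", "qc_flags"),
    select(body_water, "sample_id", body_water_enrichment = "enrichment"),
    by = "sample_id"
  )
  if (any(res$body_water_enrichment <= 0)) {
    abort(paste0(
      "Body-water enrichment must be > 0 to form the precursor ratio; ",
      "offending sample(s): ",
      paste(res$sample_id[res$body_water_enrichment <= 0], collapse = ", ")),
      class = "fgng_domain_error")
  }
  res <- mutate(res, fgng = .data$fragment_enrichment /
                  .data$body_water_enrichment)
  if (any(res$fgng > 1.05)) {
    abort(paste0(
      "fGNG > 1.05 (fragment enrichment exceeds body-water enrichment by ",
      "more than noise allows) for sample(s): ",
      paste(res$sample_id[res$fgng > 1.05], collapse = ", ")),
      class = "fgng_measurement_error")
  }
  res <- res |>
    mutate(
      qc_flags = if_else(.data$fgng > 1,
                         paste_flags(.data$qc_flags, "superunity"),
                         .data$qc_flags),
      fgng = pmin(.data$fgng, 1)
    )
  cls <- classify_feeding_state(res$fgng)
  res |>
    mutate(feeding_state = cls$feeding_state,
           overfed_flag = cls$overfed_flag) |>
    select("sample_id", "fragment_enrichment", "body_water_enrichment",
           "fgng", "feeding_state", "overfed_flag", "qc_flags")
}

paste_flags <- function(existing, flag) {
  if_else(existing == "", flag, paste(existing, flag, sep = ";"))
}

#' Classify dietary adequacy from fractional gluconeogenesis
#'
#' Bands fGNG into the dietary-adequacy states used to read the measurement
#' clinically: a fed subject makes little new glucose (fGNG 0-15%), an
#' underfed/unfed subject a lot (above 40%), and very low values (0-10%)
#' additionally suggest overfeeding. The 15-40% region is labeled
#' `indeterminate` so the three bands cover `[0, 1]` without overlap; band
#' edges are closed on the left band (`fed` includes 0.15, `unfed` excludes
#' 0.40).
#'
#' @param fgng Numeric vector of fGNG fractions in `[0, 1]`.
#' @return A tibble with columns `fgng`, `feeding_state` (factor with
#'   levels fed, indeterminate, unfed) and `overfed_flag` (logical,
#'   `fgng <= 0.10`).
#' @examples
#' classify_feeding_state(c(0, 0.12, 0.3, 0.7946))
#' @export
classify_feeding_state <- function(fgng) {
  if (any(!is.finite(fgng) | fgng < 0 | fgng > 1)) {
    abort("`fgng` values must be fractions in [0, 1].",
          class = "fgng_domain_error")
  }
  state <- cut(fgng, breaks = c(-Inf, 0.15, 0.40, Inf),
               labels = c("fed", "indeterminate", "unfed"), right = TRUE)
  tibble(fgng = fgng,
         feeding_state = factor(state,
                                levels = c("fed", "indeterminate", "unfed")),
         overfed_flag = fgng <= 0.10)
}
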