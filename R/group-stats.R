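#' Two-way factorial ANOVA on per-animal outcomes
#'
#' Fits `response ~ feeding * injury` with sum-to-zero contrasts and reports
#' Type III sums of squares — the convention matching the SPSS GLM default
#' that small-cohort animal studies typically report. With the unbalanced
#' cell counts of such cohorts (e.g. 3/6/6/5), Type I and Type III answers
#' differ, and Type III tests each main effect adjusted for the other and
#' for the interaction.
#'
#' @param records Data frame with factor columns `feeding` (levels AL, CR)
#'   and `injury` (levels Con, TBI) plus the response column.
#' @param response Name of the response column (default `"fgng"`).
#' @param ss_type Sum-of-squares type, `3` (default) or `1`.
#' @return An object of class `fgng_anova`: a list with `table` (a tibble
#'   with columns `effect`, `sum_sq`, `df`, `statistic`, `p_value`), the
#'   underlying `lm` fit, and the cell counts. `tidy()` returns the table;
#'   `glance()` one-row model summary.
#' @examples
#' rec <- tidyr::expand_grid(feeding = c("AL", "CR"), injury = c("Con", "TBI"),
#'                           rep = 1:3)
#' rec$fgng <- c(0.35, 0.36, 0.34, 0.36, 0.35, 0.37,
#'               0.79, 0.80, 0.78, 0.80, 0.79, 0.81)
#' two_way_anova(rec)
#' @export
two_way_anova <- function(records, response = "fgng", ss_type = 3) {
  records <- prepare_records(records, response)
  if (!ss_type %in% c(1, 3)) {
    abort("`ss_type` must be 1 or 3.", class = "fgng_config_error")
  }
  cells <- count(records, .data$feeding, .data$injury)
  missing_cells <- anti_join(
    expand_grid(feeding = levels(records$feeding),
                injury = levels(records$injury)),
    mutate(cells, across(c("feeding", "injury"), as.character)),
    by = c("feeding", "injury"))
  if (nrow(missing_cells) > 0) {
    abort(paste0("Empty design cell(s): ",
                 paste(missing_cells$feeding, missing_cells$injury,
                       sep = ":", collapse = ", "),
                 " — interaction model not estimable."),
          class = "fgng_design_error")
  }
  fml <- stats::as.formula(paste(response, "~ feeding * injury"))
  fit <- stats::lm(fml, data = records,
                   contrasts = list(feeding = "contr.sum",
                                    injury = "contr.sum"))
  tab <- if (ss_type == 3) {
    raw <- tryCatch(car::Anova(fit, type = 3, singular.ok = TRUE),
                    error = function(e) NULL)
    if (is.null(raw)) {
      # zero residual variance defeats car's F machinery; the 2x2 Type III
      # sums of squares are the 1-df +/-1 contrasts on the cell means
      type3_cellmeans(records, response)
    } else {
      raw <- raw[rownames(raw) != "(Intercept)", ]
      anova_raw_to_tibble(raw)
    }
  } else {
    anova_raw_to_tibble(stats::anova(fit))
  }
  # 0 residual variance: a nonzero effect SS is unambiguous (F -> Inf, p -> 0)
  resid_ss <- tab$sum_sq[tab$effect == "residual"]
  total_ss <- sum(tab$sum_sq)
  if (resid_ss <= 1e-12 * max(total_ss, 1e-300)) {
    eff <- tab$effect != "residual"
    tab$statistic[eff] <- if_else(tab$sum_sq[eff] > 0, Inf, NaN)
    tab$p_value[eff] <- if_else(tab$sum_sq[eff] > 0, 0, NA_real_)
  }
  structure(list(table = tab, fit = fit, cells = cells,
                 response = response, ss_type = ss_type),
            class = "fgng_anova")
}

#' @export
print.fgng_anova <- function(x, ...) {
  cat(sprintf("<fgng_anova> Type %s SS, response = %s\n", x$ss_type,
              x$response))
  print(as.data.frame(x$table), digits = 5)
  invisible(x)
}

#' @rdname two_way_anova
#' @param x,object An `fgng_anova`.
#' @param ... Unused.
#' @export
tidy.fgng_anova <- function(x, ...) x$table

#' @rdname two_way_anova
#' @export
glance.fgng_anova <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, sigma = s$sigma,
         df.residual = x$fit$df.residual,
         n = length(stats::residuals(x$fit)))
}

#' Independent two-sample t-test (pooled variance by default)
#'
#' Student's two-sided independent t-test with pooled variance, the
#' SPSS-reported default line for comparing two feeding groups; Welch's
#' unequal-variance form is available behind `var_equal = FALSE`. Degenerate
#' zero-variance inputs are resolved by convention: identical means give
#' `t = 0, p = 1`; different means with zero pooled variance are an error.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param var_equal Pool the variances (Student) if `TRUE` (default),
#'   else Welch.
#' @return A one-row tibble: `estimate` (mean difference a - b),
#'   `statistic`, `df`, `p_value`, `method`.
#' @examples
#' independent_t_test(c(1, 2, 3), c(4, 5, 6))
#' @export
independent_t_test <- function(group_a, group_b, var_equal = TRUE) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("Each group needs at least 2 observations.",
          class = "fgng_design_error")
  }
  method <- if (var_equal) "student" else "welch"
  if (var(group_a) == 0 && var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(tibble(estimate = 0, statistic = 0,
                    df = length(group_a) + length(group_b) - 2,
                    p_value = 1, method = method))
    }
    abort("Zero variance in both groups with unequal means: t undefined.",
          class = "fgng_degenerate_error")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = var_equal)
  tibble(estimate = mean(group_a) - mean(group_b),
         statistic = unname(ht$statistic),
         df = unname(ht$parameter),
         p_value = ht$p.value,
         method = method)
}

#' Tukey-Kramer post hoc comparisons across design cells
#'
#' Pairwise studentized-range comparisons across the four feeding x injury
#' cells, using the Tukey-Kramer adjustment for unequal cell sizes. The
#' error term is the pooled within-cell mean square — identical to the
#' residual of the full interaction model, since the cell-means one-way
#' model and the two-way model with interaction have the same residuals.
#'
#' @inheritParams two_way_anova
#' @return A tibble with columns `contrast` (e.g. `"CR:Con-AL:Con"`),
#'   `estimate`, `conf_low`, `conf_high`, `p_adj`.
#' @export
tukey_hsd <- function(records, response = "fgng") {
  records <- prepare_records(records, response)
  records$cell <- interaction(records$feeding, records$injury, sep = ":")
  cells <- count(records, .data$cell)
  if (nrow(cells) < 2) {
    abort("Tukey comparisons need >= 2 populated cells.",
          class = "fgng_design_error")
  }
  y <- records[[response]]
  if (var(y) == 0) {
    # all observations identical: every difference is exactly 0
    pairs <- utils::combn(as.character(cells$cell), 2)
    return(tibble(contrast = paste(pairs[2, ], pairs[1, ], sep = "-"),
                  estimate = 0, conf_low = 0, conf_high = 0, p_adj = 1))
  }
  fml <- stats::as.formula(paste(response, "~ cell"))
  hsd <- stats::TukeyHSD(stats::aov(fml, data = records))$cell
  tibble(contrast = rownames(hsd),
         estimate = hsd[, "diff"],
         conf_low = hsd[, "lwr"],
         conf_high = hsd[, "upr"],
         p_adj = hsd[, "p adj"])
}

#' Factorial ANOVA reconstructed from per-cell summary statistics
#'
#' Rebuilds the Type III two-way ANOVA from published per-cell means, SDs
#' and counts alone — no raw data needed. Within-cell sums of squares are
#' recovered as `sum((n - 1) * sd^2)`; each 1-df effect in the 2x2 design is
#' the sum of squares of its +/-1 contrast on the cell means,
#' `L^2 / sum(1/n)`, which for sum-to-zero contrasts is exactly the Type III
#' quantity. On any dataset sharing the summaries this reproduces
#' [two_way_anova()], making it an independent cross-check on printed group
#' tables.
#'
#' @param summaries Data frame with one row per cell and columns `feeding`,
#'   `injury`, `mean`, `sd`, `n` (all four cells, each `n >= 2`).
#' @return An `fgng_anova`-style tibble with columns `effect`, `sum_sq`,
#'   `df`, `statistic`, `p_value`.
#' @examples
#' anova_from_summary(tibble::tibble(
#'   feeding = c("AL", "AL", "CR", "CR"),
#'   injury  = c("Con", "TBI", "Con", "TBI"),
#'   mean = c(62.64, 59.85, 79.83, 79.10),
#'   sd   = c(6.33, 5.01, 4.43, 4.52),
#'   n    = c(3, 6, 6, 5)))
#' @export
anova_from_summary <- function(summaries) {
  summaries <- as_tibble(summaries)
  required <- c("feeding", "injury", "mean", "sd", "n")
  if (!all(required %in% names(summaries))) {
    abort(paste0("Summary table needs columns: ",
                 paste(required, collapse = ", ")),
          class = "fgng_validation_error")
  }
  if (nrow(distinct(summaries, .data$feeding, .data$injury)) != 4 ||
      nrow(summaries) != 4) {
    abort("Expect exactly the four feeding x injury cells.",
          class = "fgng_design_error")
  }
  if (any(summaries$n < 2)) {
    abort("Every cell needs n >= 2 to carry a variance.",
          class = "fgng_design_error")
  }
  s <- arrange(summaries, .data$feeding, .data$injury)  # AL:Con AL:TBI CR:Con CR:TBI
  c_feed <- c(1, 1, -1, -1)
  c_inj <- c(1, -1, 1, -1)
  c_int <- c_feed * c_inj
  contrast_ss <- function(cc) sum(cc * s$mean)^2 / sum(cc^2 / s$n)
  ss <- c(feeding = contrast_ss(c_feed), injury = contrast_ss(c_inj),
          interaction = contrast_ss(c_int))
  ss_res <- sum((s$n - 1) * s$sd^2)
  df_res <- sum(s$n) - 4
  ms_res <- ss_res / df_res
  f <- ss / ms_res
  tibble(effect = c(names(ss), "residual"),
         sum_sq = c(unname(ss), ss_res),
         df = c(1, 1, 1, df_res),
         statistic = c(unname(f), NA_real_),
         p_value = c(pf(unname(f), 1, df_res, lower.tail = FALSE), NA_real_))
}

anova_raw_to_tibble <- function(raw) {
  tibble(
    effect = sub("feeding:injury", "interaction", rownames(raw), fixed = TRUE),
    sum_sq = raw$`Sum Sq`,
    df = raw$Df,
    statistic = raw$`F value`,
    p_value = raw$`Pr(>F)`
  ) |>
    mutate(effect = dplyr::recode(.data$effect, Residuals = "residual"))
}

# Type III table for the full 2x2 via contrast sums of squares on cell means.
type3_cellmeans <- function(records, response) {
  s <- records |>
    group_by(.data$feeding, .data$injury) |>
    summarise(m = mean(.data[[response]]),
              ssw = sum((.data[[response]] - mean(.data[[response]]))^2),
              n = dplyr::n(), .groups = "drop") |>
    arrange(.data$feeding, .data$injury)
  c_feed <- c(1, 1, -1, -1); c_inj <- c(1, -1, 1, -1)
  cons <- list(feeding = c_feed, injury = c_inj,
               interaction = c_feed * c_inj)
  ss <- vapply(cons, function(cc) sum(cc * s$m)^2 / sum(cc^2 / s$n),
               numeric(1))
  ss_res <- sum(s$ssw)
  df_res <- sum(s$n) - 4
  ms_res <- ss_res / df_res
  f <- ss / ms_res
  tibble(effect = c(names(cons), "residual"),
         sum_sq = c(unname(ss), ss_res),
         df = c(1, 1, 1, df_res),
         statistic = c(unname(f), NA_real_),
         p_value = c(pf(unname(f), 1, df_res, lower.tail = FALSE), NA_real_))
}

# Coerce the design columns to the fixed factor vocabularies and check the
# response.
prepare_records <- function(records, response) {
  records <- as_tibble(records)
  required <- c("feeding", "injury", response)
  if (!all(required %in% names(records))) {
    abort(paste0("Records need columns: ", paste(required, collapse = ", ")),
          class = "fgng_validation_error")
  }
  bad_feed <- setdiff(unique(as.character(records$feeding)), c("AL", "CR"))
  bad_inj <- setdiff(unique(as.character(records$injury)), c("Con", "TBI"))
  if (length(bad_feed) > 0 || length(bad_inj) > 0) {
    abort(paste0("Unknown factor level(s): ",
                 paste(c(bad_feed, bad_inj), collapse = ", "),
                 " (feeding in {AL, CR}, injury in {Con, TBI})."),
          class = "fgng_validation_error")
  }
  if (any(!is.finite(records[[response]]))) {
    abort(paste0("Non-finite values in response `", response, "`."),
          class = "fgng_validation_error")
  }
  records$feeding <- factor(as.character(records$feeding),
                            levels = c("AL", "CR"))
  records$injury <- factor(as.character(records$injury),
                           levels = c("Con", "TBI"))
  records
}
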