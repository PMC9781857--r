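make_records <- function(values_by_cell) {
  purrr::imap(values_by_cell, function(v, cell) {
    parts <- strsplit(cell, ":")[[1]]
    tibble::tibble(feeding = parts[1], injury = parts[2], fgng = v)
  }) |> purrr::list_rbind()
}

test_that("two-way ANOVA handles constructed additive and degenerate designs", {
  # additive cell means, zero residual and zero interaction pattern
  rec <- make_records(list("AL:Con" = rep(1, 2), "AL:TBI" = rep(2, 2),
                           "CR:Con" = rep(3, 2), "CR:TBI" = rep(4, 2)))
  tab <- tidy(two_way_anova(rec))
  expect_equal(tab$sum_sq[tab$effect == "interaction"], 0, tolerance = 1e-12)

  # 0/1 split along feeding only: hand decomposition gives SS = 2, residual 0
  toy <- make_records(list("AL:Con" = c(0, 0), "AL:TBI" = c(0, 0),
                           "CR:Con" = c(1, 1), "CR:TBI" = c(1, 1)))
  ttab <- tidy(two_way_anova(toy))
  expect_equal(ttab$sum_sq[ttab$effect == "feeding"], 2, tolerance = 1e-12)
  expect_equal(ttab$sum_sq[ttab$effect == "residual"], 0, tolerance = 1e-12)
  expect_identical(ttab$statistic[ttab$effect == "feeding"], Inf)
  expect_identical(ttab$p_value[ttab$effect == "feeding"], 0)

  empty_cell <- make_records(list("AL:Con" = c(0.3, 0.4),
                                  "CR:Con" = c(0.7, 0.8),
                                  "CR:TBI" = c(0.6, 0.7)))
  err <- tryCatch(two_way_anova(empty_cell), error = function(e) e)
  expect_s3_class(err, "fgng_design_error")
  expect_match(conditionMessage(err), "AL:TBI")
  expect_error(two_way_anova(dplyr::mutate(toy, feeding = "XX")),
               class = "fgng_validation_error")
})

test_that("balanced designs match the brute-force cell-means oracle", {
  set.seed(303)
  for (k in 1:3) {
    rec <- make_records(list("AL:Con" = rnorm(4, 0.4, 0.05),
                             "AL:TBI" = rnorm(4, 0.5, 0.05),
                             "CR:Con" = rnorm(4, 0.7, 0.05),
                             "CR:TBI" = rnorm(4, 0.8, 0.05)))
    tab <- tidy(two_way_anova(rec))
    oracle <- balanced_anova_oracle(rec)
    for (eff in names(oracle)) {
      expect_equal(tab$sum_sq[tab$effect == eff], unname(oracle[eff]),
                   tolerance = 1e-9)
    }
    # SS decomposition: effects + residual = total
    expect_equal(sum(tab$sum_sq), sum((rec$fgng - mean(rec$fgng))^2),
                 tolerance = 1e-9)
  }
})

test_that("pooled t-test matches hand computation and conventions", {
  ht <- independent_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ht$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(ht$df, 4)

  same <- independent_t_test(c(2, 2), c(2, 2))
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)
  expect_error(independent_t_test(c(1, 1), c(2, 2)),
               class = "fgng_degenerate_error")
  expect_error(independent_t_test(1, c(2, 3)), class = "fgng_design_error")

  # t^2 equals the one-factor two-level ANOVA F on the same data
  set.seed(7)
  a <- rnorm(8, 0.4, 0.1); b <- rnorm(5, 0.6, 0.1)
  t2 <- independent_t_test(a, b)$statistic^2
  f_tab <- stats::anova(stats::lm(y ~ g, data = data.frame(
    y = c(a, b), g = rep(c("a", "b"), c(8, 5)))))
  expect_equal(t2, f_tab$`F value`[1], tolerance = 1e-9)

  welch <- independent_t_test(a, b, var_equal = FALSE)
  expect_identical(welch$method, "welch")
  expect_false(isTRUE(all.equal(welch$df, 11)))
})

test_that("Tukey-Kramer comparisons behave across separation regimes", {
  const <- make_records(list("AL:Con" = rep(0.5, 3), "AL:TBI" = rep(0.5, 3),
                             "CR:Con" = rep(0.5, 3), "CR:TBI" = rep(0.5, 3)))
  tk <- tukey_hsd(const)
  expect_identical(tk$p_adj, rep(1, 6))
  expect_identical(tk$estimate, rep(0, 6))

  set.seed(99)
  mixed <- make_records(list(
    "AL:Con" = rnorm(5, 0.30, 0.01), "AL:TBI" = rnorm(6, 0.80, 0.01),
    "CR:Con" = rnorm(5, 0.55, 0.01), "CR:TBI" = rnorm(4, 0.55, 0.01)))
  tk2 <- tukey_hsd(mixed)
  far <- tk2$p_adj[tk2$contrast == "AL:TBI-AL:Con"]
  near <- tk2$p_adj[tk2$contrast == "CR:TBI-CR:Con"]
  expect_lt(far, 0.001)
  expect_gt(near, 0.5)
})

test_that("summary-statistics ANOVA reproduces the raw-data Type III table", {
  cells <- tibble::tibble(
    feeding = c("AL", "AL", "CR", "CR"),
    injury = c("Con", "TBI", "Con", "TBI"),
    mean = c(0.62, 0.58, 0.80, 0.77),
    sd = c(0.06, 0.05, 0.045, 0.05),
    n = c(3, 6, 6, 5))
  rec <- purrr::pmap(cells, function(feeding, injury, mean, sd, n) {
    tibble::tibble(feeding = feeding, injury = injury,
                   fgng = exact_moments(n, mean, sd))
  }) |> purrr::list_rbind()
  from_raw <- tidy(two_way_anova(rec))
  from_sum <- anova_from_summary(cells)
  expect_equal(from_sum$sum_sq, from_raw$sum_sq, tolerance = 1e-9)
  expect_equal(from_sum$statistic[1:3], from_raw$statistic[1:3],
               tolerance = 1e-9)
  expect_equal(from_sum$p_value[1:3], from_raw$p_value[1:3],
               tolerance = 1e-9)

  flat <- dplyr::mutate(cells, mean = 0.5)
  expect_equal(anova_from_summary(flat)$sum_sq[1:3], rep(0, 3),
               tolerance = 1e-12)
  expect_error(anova_from_summary(dplyr::mutate(cells, n = c(1, 6, 6, 5))),
               class = "fgng_design_error")
})

test_that("published post-intervention summaries give a decisive feeding effect", {
  printed <- tibble::tibble(
    feeding = c("AL", "AL", "CR", "CR"),
    injury = c("Con", "TBI", "Con", "TBI"),
    mean = c(62.64, 59.85, 79.83, 79.10),
    sd = c(6.33, 5.01, 4.43, 4.52),
    n = c(3, 6, 6, 5))
  tab <- anova_from_summary(printed)
  expect_lt(tab$p_value[tab$effect == "feeding"], 0.001)
  expect_gt(tab$p_value[tab$effect == "injury"], 0.05)
  expect_gt(tab$p_value[tab$effect == "interaction"], 0.05)
})
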