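test_that("labeling distribution matches hand-evaluated binomial mixture", {
  fr <- fragment_model()

  # no label in the water: everything stays at mass shift 0
  d0 <- label_distribution(0, 0.7, fr, mode = "binomial")
  expect_equal(d0, c(1, rep(0, 6)))

  # fully gluconeogenic pool at 6% body water: M+1 mass is 6 p (1-p)^5
  d1 <- label_distribution(0.06, 1, fr, mode = "binomial")
  expect_length(d1, 7)
  expect_equal(d1[2], 6 * 0.06 * 0.94^5, tolerance = 1e-12)

  # linear mode: M+1/M ratio is fgng * n_sites * p_water
  dl <- label_distribution(0.06, 0.5, fr, mode = "linear")
  expect_length(dl, 2)
  expect_equal(dl[2] / dl[1], 0.5 * 6 * 0.06, tolerance = 1e-12)

  expect_error(label_distribution(-0.01, 0.5, fr), class = "fgng_domain_error")
  expect_error(label_distribution(0.06, 1.2, fr), class = "fgng_domain_error")
})

test_that("distributions are proper and the M+1/M ratio is monotone", {
  fr <- fragment_model()
  grid <- tidyr::expand_grid(p = c(0.01, 0.03, 0.06, 0.1, 0.3),
                             f = c(0.1, 0.35, 0.6, 0.9))
  for (i in seq_len(nrow(grid))) {
    for (mode in c("binomial", "linear")) {
      d <- label_distribution(grid$p[i], grid$f[i], fr, mode = mode)
      expect_true(all(d >= 0))
      expect_equal(sum(d), 1, tolerance = 1e-12)
    }
  }
  ratio <- function(p, f) {
    d <- label_distribution(p, f, fr, mode = "binomial")
    d[2] / d[1]
  }
  # monotone in fgng over (0,1); monotone in p_water below the single-label
  # turnover at p = 1/n_sites (beyond it, M+1 mass migrates to M+2 and up)
  ps <- seq(0.005, 1 / 6 - 0.005, length.out = 25)
  fs <- seq(0.01, 0.99, length.out = 25)
  expect_true(all(diff(vapply(ps, ratio, numeric(1), f = 0.5)) > 0))
  expect_true(all(diff(vapply(fs, ratio, numeric(1), p = 0.06)) > 0))
})

test_that("linear and binomial modes agree to first order at low enrichment", {
  fr <- fragment_model()
  gap <- function(p, f) {
    db <- label_distribution(p, f, fr, mode = "binomial")
    dl <- label_distribution(p, f, fr, mode = "linear")
    abs(db[2] / db[1] - dl[2] / dl[1]) / (dl[2] / dl[1])
  }
  # the relative gap is first order in n_sites * p_water and vanishes with p
  for (f in c(0.2, 0.6, 1)) {
    gaps <- vapply(c(0.01, 0.005, 0.002, 0.001), gap, numeric(1), f = f)
    expect_true(all(gaps < 6 * c(0.01, 0.005, 0.002, 0.001)))
    expect_true(all(diff(gaps) < 0))
  }
  expect_lt(gap(0.001, 0.5), 0.005)
})

test_that("binomial mode agrees with explicit 2^n site enumeration", {
  fr <- fragment_model()
  for (p in c(0.03, 0.06)) {
    for (f in c(0.35, 0.8)) {
      expect_equal(label_distribution(p, f, fr, mode = "binomial"),
                   label_dist_enum(p, f, 6), tolerance = 1e-12)
    }
  }
})

test_that("natural-abundance M+1 ratio follows the pinned isotope table", {
  expect_identical(natural_abundance_m1(fragment_model()), 0)
  one_c <- fragment_model(composition = c(C = 1))
  expect_equal(natural_abundance_m1(one_c), 0.0107 / 0.9893,
               tolerance = 1e-9)
  # 8 carbons: exact polynomial expansion vs the first-order 8x sum
  eight_c <- fragment_model(composition = c(C = 8))
  exact <- natural_abundance_m1(eight_c)
  table <- isotope_abundances()
  brute <- Reduce(conv_oracle, rep(list(table$C), 8))
  expect_equal(exact, brute[2] / brute[1], tolerance = 1e-10)
  expect_equal(exact, 8 * 0.0107 / 0.9893, tolerance = 0.01 * exact)
  expect_error(natural_abundance_m1(fragment_model(composition = c(Xx = 2))),
               class = "fgng_config_error")
})

test_that("background convolution matches hand and brute-force results", {
  fr_off <- fragment_model()
  d <- label_distribution(0.06, 0.5, fr_off, mode = "binomial")
  expect_identical(convolve_background(d, fr_off), d)

  # hand-convolved example
  expect_equal(convolve_probs(c(0.9, 0.1), c(0.95, 0.05)),
               c(0.855, 0.14, 0.005), tolerance = 1e-12)

  # a pure point mass picks up exactly the background ratio
  fr_c <- fragment_model(composition = c(C = 6, H = 7, O = 4))
  point <- c(1, 0, 0)
  out <- convolve_background(point, fr_c)
  expect_equal(out[2] / out[1], natural_abundance_m1(fr_c), tolerance = 1e-12)

  # random small distributions vs the double-sum oracle
  set.seed(11)
  for (k in 1:5) {
    a <- runif(4); a <- a / sum(a)
    b <- runif(3); b <- b / sum(b)
    expect_equal(convolve_probs(a, b), conv_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("fragment model validates its geometry", {
  expect_error(fragment_model(n_sites = 0), class = "fgng_domain_error")
  expect_error(fragment_model(base_mz = -1), class = "fgng_domain_error")
  expect_error(fragment_model(composition = c(C = -2)),
               class = "fgng_config_error")
  expect_error(fragment_model(composition = 3), class = "fgng_config_error")
  fr <- fragment_model()
  expect_identical(fr$n_sites, 6L)
  expect_identical(fr$base_mz, 169L)
})
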