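#' Describe the monitored glucose-derivative fragment
#'
#' The deuterium readout of the pipeline is the m/z 169/170 isotopologue pair
#' of the glucose penta-acetate derivative. The m/z 169 fragment carries six
#' hydrogens (carbons 1, 3, 4, 5 and 6) that can exchange with deuterium
#' during gluconeogenesis; it deliberately lacks the carbon-2 hydrogen, whose
#' labeling reflects total glucose turnover rather than gluconeogenesis alone.
#' A `fragment_model` records that labeling geometry plus an optional
#' elemental composition used only for natural-abundance background
#' modeling.
#'
#' @param n_sites Number of deuterium-exchangeable hydrogens monitored.
#'   Default 6, the constant that divides the M+1/M ratio in the enrichment
#'   equation.
#' @param base_mz Nominal m/z of the unlabeled monitored ion (default 169).
#' @param composition Named numeric vector of atom counts (e.g.
#'   `c(C = 8, H = 11, O = 5)`) used to compute the natural-abundance M+1
#'   background. The default is empty, meaning no background is modeled —
#'   the raw-ratio convention of the enrichment equation. The true elemental
#'   composition of the m/z 169 ion is instrument- and chemistry-dependent,
#'   so it is a configuration value, never an assumption baked into results.
#'
#' @return An object of class `fragment_model`.
#' @examples
#' fragment_model()
#' fragment_model(composition = c(C = 8, H = 11, O = 5))
#' @export
fragment_model <- function(n_sites = 6L, base_mz = 169L, composition = NULL) {
  n_sites <- as.integer(n_sites)
  base_mz <- as.integer(base_mz)
  if (is.na(n_sites) || n_sites < 1L) {
    abort("`n_sites` must be an integer >= 1.", class = "fgng_domain_error")
  }
  if (is.na(base_mz) || base_mz <= 0L) {
    abort("`base_mz` must be a positive integer.", class = "fgng_domain_error")
  }
  composition <- composition %||% stats::setNames(numeric(0), character(0))
  if (length(composition) > 0) {
    if (is.null(names(composition)) || any(names(composition) == "")) {
      abort("`composition` must be a named vector of atom counts.",
            class = "fgng_config_error")
    }
    if (any(composition < 0) || any(composition != floor(composition))) {
      abort("Atom counts in `composition` must be non-negative integers.",
            class = "fgng_config_error")
    }
    composition <- composition[composition > 0]
  }
  structure(
    list(n_sites = n_sites, base_mz = base_mz, composition = composition),
    class = "fragment_model"
  )
}

#' @export
print.fragment_model <- function(x, ...) {
  cat("<fragment_model> m/z", x$base_mz, "ion,", x$n_sites,
      "exchangeable H sites\n")
  if (length(x$composition) == 0) {
    cat("  natural-abundance background: disabled (empty composition)\n")
  } else {
    cat("  composition:",
        paste0(names(x$composition), x$composition, collapse = " "), "\n")
  }
  invisible(x)
}

#' Pinned natural-abundance isotope table
#'
#' Reads the isotope-abundance table shipped with the package: for each
#' element, the mole fraction of isotopologues at each nominal mass shift
#' (0, +1, +2, ...) relative to the lightest isotope. The table is a static
#' packaged file so that background corrections are reproducible.
#'
#' @return Named list; each element is a numeric probability vector indexed
#'   from mass shift 0.
#' @export
isotope_abundances <- function() {
  path <- system.file("extdata", "isotope_abundances.json", package = "fgng",
                      mustWork = TRUE)
  raw <- jsonlite::read_json(path)$elements
  lapply(raw, function(el) {
    shifts <- as.integer(names(el))
    p <- numeric(max(shifts) + 1L)
    p[shifts + 1L] <- as.numeric(unlist(el))
    p / sum(p)
  })
}

#' Convolve two mass-shift probability distributions
#'
#' Discrete convolution of two isotopologue (mass-shift) distributions:
#' the distribution of the sum of two independent integer mass shifts.
#' This is the primitive behind multi-atom natural-abundance expansion and
#' background convolution.
#'
#' @param a,b Numeric probability vectors indexed from shift 0.
#' @return Numeric vector of length `length(a) + length(b) - 1`.
#' @examples
#' convolve_probs(c(0.9, 0.1), c(0.95, 0.05))
#' @export
convolve_probs <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Natural-abundance mass-shift distribution of a fragment
#'
#' Expands the fragment's elemental composition into the distribution of
#' total nominal mass shift arising from naturally occurring heavy isotopes
#' (chiefly 13C), by exact polynomial convolution over all atoms. An empty
#' composition yields the degenerate distribution at shift 0 (no
#' background).
#'
#' @param fragment A [fragment_model()].
#' @param truncate_at Drop (and renormalize away) shifts beyond this value;
#'   default keeps shifts up to +4, ample for small organic ions.
#' @return Numeric probability vector indexed from shift 0.
#' @export
background_distribution <- function(fragment, truncate_at = 4L) {
  stopifnot(inherits(fragment, "fragment_model"))
  comp <- fragment$composition
  if (length(comp) == 0) return(1)
  table <- isotope_abundances()
  unknown <- setdiff(names(comp), names(table))
  if (length(unknown) > 0) {
    abort(paste0("Unknown element symbol(s) in composition: ",
                 paste(unknown, collapse = ", ")),
          class = "fgng_config_error")
  }
  dist <- 1
  for (el in names(comp)) {
    for (k in seq_len(comp[[el]])) {
      dist <- convolve_probs(dist, table[[el]])
      if (length(dist) > truncate_at + 1L) {
        dist <- dist[seq_len(truncate_at + 1L)]
      }
    }
  }
  dist / sum(dist)
}

#' Natural-abundance M+1/M ratio of a fragment
#'
#' The ratio of the +1 to the +0 mass-shift probabilities from the
#' fragment's elemental composition — the M+1 signal an unlabeled analyte
#' contributes per unit of M signal. Returns 0 for an empty composition.
#'
#' @inheritParams background_distribution
#' @return A single non-negative number.
#' @examples
#' natural_abundance_m1(fragment_model(composition = c(C = 1)))
#' @export
natural_abundance_m1 <- function(fragment) {
  bg <- background_distribution(fragment)
  if (length(bg) < 2L) return(0)
  bg[2] / bg[1]
}

#' Forward model: isotopologue distribution of partly gluconeogenic glucose
#'
#' Models circulating glucose as a mixture: a fraction `fgng_true` made de
#' novo while body water contains a deuterium fraction `p_water` (each of the
#' fragment's `n_sites` exchangeable hydrogens independently deuterated with
#' probability `p_water`), and the remainder unlabeled at those sites
#' (glycogenolysis of pre-label stores). Two modes:
#'
#' * `"binomial"` — the exact mixture `fgng_true * Binomial(n_sites, p_water)
#'   + (1 - fgng_true) * delta_0`, length `n_sites + 1`.
#' * `"linear"` — the first-order truncation in which the M+1 excess over M
#'   is `fgng_true * n_sites * p_water`, length 2. This is the implicit
#'   assumption of the ratio-divided-by-six enrichment equation.
#'
#' Natural-abundance background is *not* included here; see
#' [convolve_background()].
#'
#' @param p_water Deuterium fraction of body water, in `[0, 1]`.
#' @param fgng_true True fractional gluconeogenesis, in `[0, 1]`.
#' @param fragment A [fragment_model()].
#' @param mode `"binomial"` (exact) or `"linear"` (first-order).
#' @return Numeric probability vector over mass shifts 0, 1, ...; sums to 1.
#' @examples
#' label_distribution(0.06, 1, fragment_model())[2]   # 6 * .06 * .94^5
#' label_distribution(0.06, 0.5, fragment_model(), mode = "linear")
#' @export
label_distribution <- function(p_water, fgng_true, fragment = fragment_model(),
                               mode = c("binomial", "linear")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fragment, "fragment_model"))
  if (!is.finite(p_water) || p_water < 0 || p_water > 1) {
    abort("`p_water` must be a fraction in [0, 1].",
          class = "fgng_domain_error")
  }
  if (!is.finite(fgng_true) || fgng_true < 0 || fgng_true > 1) {
    abort("`fgng_true` must be a fraction in [0, 1].",
          class = "fgng_domain_error")
  }
  n <- fragment$n_sites
  if (mode == "binomial") {
    gng <- stats::dbinom(0:n, size = n, prob = p_water)
    p <- fgng_true * gng
    p[1] <- p[1] + (1 - fgng_true)
  } else {
    r <- fgng_true * n * p_water
    p <- c(1, r) / (1 + r)
  }
  p / sum(p)
}

#' Add natural-abundance background to a labeling distribution
#'
#' Convolves a labeling isotopologue distribution with the fragment's
#' natural-abundance mass-shift distribution (the two sources of mass shift
#' are independent), truncates to the input length plus the background
#' support, and renormalizes. With an empty composition the input is
#' returned unchanged.
#'
#' @param labeled Numeric probability vector over mass shifts (from
#'   [label_distribution()]).
#' @param fragment A [fragment_model()].
#' @return Numeric probability vector; sums to 1.
#' @export
convolve_background <- function(labeled, fragment) {
  check_distribution(labeled)
  bg <- background_distribution(fragment)
  if (length(bg) == 1L) return(labeled)
  out <- convolve_probs(labeled, bg)
  out / sum(out)
}

# Internal: validate an isotopologue probability vector.
check_distribution <- function(p, tol = 1e-12) {
  if (any(!is.finite(p)) || any(p < -tol) || any(p > 1 + tol)) {
    abort("Isotopologue probabilities must lie in [0, 1].",
          class = "fgng_domain_error")
  }
  if (abs(sum(p) - 1) > 1e-8) {
    abort("Isotopologue probabilities must sum to 1.",
          class = "fgng_domain_error")
  }
  invisible(p)
}
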