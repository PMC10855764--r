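#' Dose-response template for a VOC class
#'
#' Describes the expected IS-normalized area of a chemical class as a function
#' of absorbed dose (kGy), on which multiplicative log-normal noise is layered
#' by the generator. Four shapes are supported:
#' \describe{
#'   \item{`monotone_up`}{linear increase, reaching `base_level * effect_size`
#'     at the top dose; with `zero_at_control = TRUE` the level is an exact
#'     structural zero at dose 0 (radiolytic hydrocarbons appear only in
#'     irradiated samples).}
#'   \item{`peak_mid`}{quadratic with its vertex at 4.0 kGy, where the level is
#'     `base_level * effect_size`; production and degradation compete so the
#'     top dose falls back toward the control level.}
#'   \item{`flat`}{constant at `base_level`.}
#'   \item{`down`}{linear decrease to `base_level / effect_size` at the top
#'     dose (packaging-derived contaminants).}
#' }
#'
#' @param class_name VOC chemical class label.
#' @param pattern One of `"monotone_up"`, `"peak_mid"`, `"flat"`, `"down"`.
#' @param base_level Expected level at dose 0 (dimensionless, > 0).
#' @param effect_size Fold change at the pattern maximum (>= 1 for
#'   `monotone_up` and `peak_mid`).
#' @param noise_sigma Standard deviation of the log-scale noise (>= 0).
#' @param zero_at_control Structural zero at dose 0 (only meaningful for
#'   `monotone_up`).
#' @return Object of class `dose_template`.
#' @export
dose_response_template <- function(class_name,
                                   pattern = c("monotone_up", "peak_mid",
                                               "flat", "down"),
                                   base_level = 1, effect_size = 4,
                                   noise_sigma = 0.15,
                                   zero_at_control = FALSE) {
  pattern <- match.arg(pattern)
  stopifnot(base_level > 0, noise_sigma >= 0, effect_size > 0)
  if (pattern %in% c("monotone_up", "peak_mid") && effect_size < 1) {
    stop("effect_size must be >= 1 for increasing/peaked patterns", call. = FALSE)
  }
  structure(list(class_name = class_name, pattern = pattern,
                 base_level = base_level, effect_size = effect_size,
                 noise_sigma = noise_sigma, zero_at_control = zero_at_control),
            class = "dose_template")
}

#' Expected level of a template at given doses
#'
#' @param template A [dose_response_template()].
#' @param dose Numeric dose vector in kGy (the study domain is 0--6).
#' @param base_level Optional per-compound base level overriding the template's.
#' @param effect_size Optional per-compound effect size overriding the
#'   template's.
#' @return Numeric vector of expected (noise-free) levels.
#' @export
template_level <- function(template, dose, base_level = NULL,
                           effect_size = NULL) {
  stopifnot(inherits(template, "dose_template"))
  b <- base_level %||% template$base_level
  e <- effect_size %||% template$effect_size
  top <- 6  # highest study dose; templates are parameterized on 0..6 kGy
  switch(template$pattern,
    monotone_up = if (isTRUE(template$zero_at_control)) {
      b * e * dose / top
    } else {
      b * (1 + (e - 1) * dose / top)
    },
    peak_mid = b * (1 + (e - 1) * (1 - ((dose - 4) / 4)^2)),
    flat = rep(b, length(dose)),
    down = b * (1 + (1 / e - 1) * dose / top)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_class_counts <- function(cheese) {
  switch(cheese,
    brie = c(alcohols = 9L, aldehydes = 1L, alkanes = 6L, alkenes = 4L,
             aromatics = 1L, carboxylic_acids = 10L, esters = 2L,
             ketones = 10L, methyl_esters = 16L, other = 2L,
             sulfur_compounds = 1L, terpenes = 1L),
    camembert = c(alcohols = 12L, aldehydes = 4L, alkanes = 7L, alkenes = 4L,
                  alkynes = 1L, aromatics = 2L, carboxylic_acids = 11L,
                  ketones = 9L, methyl_esters = 16L, lactones = 2L,
                  other = 4L, sulfur_compounds = 7L),
    stop("unknown cheese ", cheese, call. = FALSE))
}

# number of strong-effect "planted marker" VOCs per responsive class, sized to
# mimic the scale of the reported discriminant contributor lists (14 for Brie,
# 15 for Camembert, hydrocarbons included)
default_marker_counts <- function(cheese) {
  switch(cheese,
    brie = c(alcohols = 2L, esters = 1L, ketones = 3L, terpenes = 1L),
    camembert = c(alcohols = 2L, aldehydes = 1L, ketones = 2L,
                  sulfur_compounds = 1L))
}

default_class_patterns <- function() {
  c(alcohols = "peak_mid", aldehydes = "monotone_up", alkanes = "monotone_up",
    alkenes = "monotone_up", alkynes = "monotone_up", aromatics = "flat",
    carboxylic_acids = "peak_mid", esters = "peak_mid", ketones = "peak_mid",
    methyl_esters = "peak_mid", lactones = "peak_mid",
    sulfur_compounds = "peak_mid", terpenes = "peak_mid", other = "down")
}

#' Configure a synthetic irradiation study
#'
#' Captures the sampling design of the emulated study: 45 non-irradiated
#' control analyses plus 15 at each of 2.0, 4.0 and 6.0 kGy (90 in total), and
#' 63 (Brie) or 79 (Camembert) VOCs across 12 chemical classes.
#'
#' @param cheese `"brie"` or `"camembert"`.
#' @param n_control Control sample count (default 45).
#' @param n_per_dose Samples per irradiated dose level (default 15).
#' @param doses Dose levels in kGy; the first must be the 0-kGy control.
#' @param class_counts Named integer vector, VOCs per class; defaults to the
#'   per-cheese composition above.
#' @param marker_counts Named integer vector of planted strong-effect markers
#'   per class (hydrocarbon classes are structurally discriminant and need no
#'   planting).
#' @param effect_size Fold change of marker compounds at the template maximum.
#' @param weak_fraction Fraction of the marker effect (above 1) retained by
#'   non-marker compounds of responsive classes.
#' @param noise_sigma Log-scale noise standard deviation.
#' @param shape_jitter Amount of per-compound dose-response shape
#'   heterogeneity in [0, 1]: individual compounds of a monotone class differ
#'   in curvature and those of a peaked class in how steeply they rise to and
#'   fall from the 4.0 kGy maximum, while every compound keeps its class's
#'   qualitative shape. Real VOC classes are heterogeneous in exactly this
#'   way, and without it the dose signatures of all compounds would be
#'   confined to a two-dimensional manifold on which intermediate doses are
#'   nearly indistinguishable.
#' @param hexane_exception Keep the first alkane detectable in controls,
#'   mimicking the one alkane reported in non-irradiated samples (Brie
#'   default `TRUE`).
#' @param seed Integer seed.
#' @return Object of class `study_config`.
#' @export
study_config <- function(cheese = c("camembert", "brie"),
                         n_control = 45L, n_per_dose = 15L,
                         doses = c(0, 2, 4, 6),
                         class_counts = NULL,
                         marker_counts = NULL,
                         effect_size = 4,
                         weak_fraction = 0.15,
                         noise_sigma = 0.15,
                         shape_jitter = 1,
                         hexane_exception = NULL,
                         seed = 1L) {
  cheese <- match.arg(cheese)
  # accept plain lists (e.g. from a JSON config) as well as named vectors
  class_counts <- unlist(class_counts) %||% default_class_counts(cheese)
  marker_counts <- unlist(marker_counts) %||% default_marker_counts(cheese)
  doses <- unlist(doses)
  hexane_exception <- hexane_exception %||% (cheese == "brie")
  stopifnot(n_control >= 1L, n_per_dose >= 1L, doses[1] == 0,
            all(class_counts >= 1L), noise_sigma >= 0, effect_size >= 1,
            weak_fraction >= 0, weak_fraction <= 1)
  if (any(!names(marker_counts) %in% names(class_counts))) {
    stop("marker_counts refer to unknown classes", call. = FALSE)
  }
  if (any(marker_counts > class_counts[names(marker_counts)])) {
    stop("more planted markers than compounds in a class", call. = FALSE)
  }
  stopifnot(shape_jitter >= 0, shape_jitter <= 1)
  structure(list(cheese = cheese, n_control = as.integer(n_control),
                 n_per_dose = as.integer(n_per_dose), doses = doses,
                 class_counts = class_counts, marker_counts = marker_counts,
                 effect_size = effect_size, weak_fraction = weak_fraction,
                 noise_sigma = noise_sigma, shape_jitter = shape_jitter,
                 hexane_exception = hexane_exception,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Default class templates for a study configuration
#'
#' @param config A [study_config()].
#' @return Named list of [dose_response_template()]s, one per class in
#'   `config$class_counts`. Hydrocarbon classes (alkanes, alkenes, alkynes)
#'   are monotone increasing with a structural zero at dose 0.
#' @export
default_templates <- function(config) {
  stopifnot(inherits(config, "study_config"))
  patterns <- default_class_patterns()
  lapply(stats::setNames(nm = names(config$class_counts)), function(cl) {
    pat <- patterns[[cl]] %||% "flat"
    dose_response_template(
      class_name = cl, pattern = pat,
      base_level = 1, effect_size = config$effect_size,
      noise_sigma = config$noise_sigma,
      zero_at_control = cl %in% c("alkanes", "alkenes", "alkynes"))
  })
}

#' Generate a synthetic VOC feature table
#'
#' Draws a complete samples-by-compound table with the study's dose-response
#' structure: each entry is the template's expected level at the sample's
#' dose times `exp(N(0, noise_sigma))`. Per-compound base levels are spread
#' log-uniformly over roughly two orders of magnitude to imitate the dynamic
#' range of IS-normalized areas. Within each responsive class, the configured
#' number of planted markers carries the full effect size while the remaining
#' compounds carry an attenuated effect (`1 + weak_fraction * (effect - 1)`).
#' Hydrocarbon compounds are exact structural zeros at dose 0 (except a
#' configurable n-hexane-like first alkane). The ground-truth discriminant
#' set -- structural zeros plus planted markers -- is attached as the
#' `discriminant` attribute.
#'
#' @param config A [study_config()].
#' @param templates Named list of class templates; defaults to
#'   [default_templates()].
#' @return A `voc_table` (see [build_feature_table()]) with attributes
#'   `class_map` and `discriminant`.
#' @export
generate_voc_table <- function(config, templates = default_templates(config)) {
  stopifnot(inherits(config, "study_config"))
  missing_t <- setdiff(names(config$class_counts), names(templates))
  if (length(missing_t) > 0L) {
    stop("no template for class(es): ", paste(missing_t, collapse = ", "),
         call. = FALSE)
  }

  irr_doses <- config$doses[-1]
  dose_vec <- c(rep(0, config$n_control),
                rep(irr_doses, each = config$n_per_dose))
  n <- length(dose_vec)
  sample_id <- sprintf("%s_d%s_s%02d", config$cheese,
                       gsub("\\.", "p", format(dose_vec)), seq_len(n))

  compound <- unlist(lapply(names(config$class_counts), function(cl) {
    sprintf("%s_%02d", sub("s$", "", cl), seq_len(config$class_counts[[cl]]))
  }), use.names = FALSE)
  class_map <- stats::setNames(
    rep(names(config$class_counts), config$class_counts), compound)

  withr::with_seed(config$seed, {
    m <- matrix(0, n, length(compound), dimnames = list(sample_id, compound))
    discriminant <- character(0)
    col <- 0L
    for (cl in names(config$class_counts)) {
      tmpl <- templates[[cl]]
      n_cl <- config$class_counts[[cl]]
      n_marker <- config$marker_counts[cl]
      n_marker <- if (is.na(n_marker)) 0L else n_marker
      structural <- isTRUE(tmpl$zero_at_control)
      for (j in seq_len(n_cl)) {
        col <- col + 1L
        base <- exp(stats::runif(1, log(0.05), log(5)))
        is_marker <- j <= n_marker || structural
        eff <- if (is_marker) tmpl$effect_size else
          1 + config$weak_fraction * (tmpl$effect_size - 1)
        this_tmpl <- tmpl
        if (structural && cl == "alkanes" && j == 1L &&
            isTRUE(config$hexane_exception)) {
          # the n-hexane-like exception: detectable in controls after all
          this_tmpl$zero_at_control <- FALSE
          is_marker <- FALSE
        }
        mu <- compound_level(this_tmpl, dose_vec, base = base, effect = eff,
                             jitter = config$shape_jitter)
        noise <- exp(stats::rnorm(n, 0, tmpl$noise_sigma))
        vals <- mu * noise
        vals[mu == 0] <- 0  # structural zeros stay exact
        m[, col] <- vals
        if (is_marker) discriminant <- c(discriminant, compound[col])
      }
    }
  })

  df <- data.frame(sample_id = sample_id, cheese = config$cheese,
                   dose_kgy = dose_vec, m,
                   check.names = FALSE, row.names = NULL)
  new_voc_table(df, class_map = class_map, discriminant = discriminant)
}

# Per-compound dose-response with shape heterogeneity. Individual compounds
# deviate from the class template in curvature (monotone classes) or in the
# rise/fall fractions around the 4.0 kGy maximum (peaked classes), but every
# compound keeps the class's qualitative invariants: strictly increasing for
# monotone_up, unimodal with the maximum at 4.0 kGy for peak_mid. Consumes
# random draws, so must run inside the generator's seeded stream.
compound_level <- function(template, dose, base, effect, jitter) {
  if (jitter <= 0 || template$pattern %in% c("flat", "down")) {
    return(template_level(template, dose, base_level = base,
                          effect_size = effect))
  }
  top <- 6
  switch(template$pattern,
    monotone_up = {
      g <- exp(stats::runif(1, -0.5, 0.5) * 1.5 * jitter)  # curvature exponent
      frac <- (dose / top)^g
      if (isTRUE(template$zero_at_control)) {
        base * effect * frac
      } else {
        base * (1 + (effect - 1) * frac)
      }
    },
    peak_mid = {
      # fraction of the maximum effect reached at 2 kGy and retained at
      # 6 kGy; 0.75/0.75 (the symmetric quadratic) is the jitter-free case
      s2 <- 0.75 + stats::runif(1, -0.45, 0.2) * jitter
      s6 <- 0.75 + stats::runif(1, -0.45, 0.2) * jitter
      s <- c(0, s2, 1, s6)[match(dose, c(0, 2, 4, 6))]
      base * (1 + (effect - 1) * s)
    })
}

#' Generate a chromatogram-level peak fixture
#'
#' Emits per-sample peak records exercising the retention-index and
#' internal-standard machinery: an n-alkane ladder (C7--C30, mildly convex
#' retention program), one internal-standard peak (quantifier m/z 59, fixed
#' area) and analyte peaks whose retention times are placed by inverting the
#' van den Dool interpolation, so the ground-truth LRI of every analyte is
#' known exactly, as is its IS-normalized area.
#'
#' @param config A [study_config()].
#' @param n_samples Number of samples to emit peaks for.
#' @param truth_lri Ground-truth retention indices of the analytes.
#' @param is_area Internal-standard area (counts).
#' @return List with `peaks` (data frame `sample_id, compound, rt_min, mz,
#'   area`), `ladder` (an [alkane_ladder()]), `truth` (data frame with
#'   compound, LRI and expected normalized area).
#' @export
generate_peak_fixture <- function(config, n_samples = 3L,
                                  truth_lri = c(800, 925, 1000, 1050, 1462.5),
                                  is_area = 1e5) {
  stopifnot(inherits(config, "study_config"), n_samples >= 1L, is_area > 0)
  carbons <- 7:30
  # mildly convex program: later alkanes spread further apart
  rt <- 2 + 0.8 * (carbons - 7) + 0.01 * (carbons - 7)^2
  ladder <- alkane_ladder(carbons, rt)
  if (any(truth_lri < 700 | truth_lri > 3000)) {
    stop("ground-truth LRI outside the C7-C30 ladder span", call. = FALSE)
  }
  lri_to_rt <- function(lri) {
    nlow <- pmin(floor(lri / 100), 29)
    i <- match(nlow, ladder$carbon)
    frac <- lri / 100 - nlow
    ladder$rt_min[i] + frac * (ladder$rt_min[i + 1L] - ladder$rt_min[i])
  }
  analyte_rt <- lri_to_rt(truth_lri)
  analyte <- sprintf("analyte_%02d", seq_along(truth_lri))

  withr::with_seed(config$seed, {
    norm_area <- round(exp(stats::runif(length(truth_lri), log(0.2), log(5))), 3)
    peaks <- do.call(rbind, lapply(seq_len(n_samples), function(s) {
      sid <- sprintf("%s_fix_s%02d", config$cheese, s)
      rbind(
        data.frame(sample_id = sid, compound = "IS_3-octanol",
                   rt_min = lri_to_rt(995), mz = 59L, area = is_area),
        data.frame(sample_id = sid, compound = analyte,
                   rt_min = analyte_rt, mz = 43L,
                   area = norm_area * is_area)
      )
    }))
  })
  rownames(peaks) <- NULL
  list(peaks = peaks, ladder = ladder,
       truth = data.frame(compound = analyte, lri = truth_lri,
                          norm_area = norm_area))
}

#' Simulate responses on a central composite design
#'
#' Evaluates ground-truth quadratic surfaces on the coded design runs and adds
#' Gaussian noise, providing fixtures for response-surface recovery tests.
#'
#' @param design A `ccd_design`.
#' @param truth Named list of `quadratic_surface` objects (e.g.
#'   `list(y1 = ..., y2 = ...)`).
#' @param noise_sigma Standard deviation of additive response noise.
#' @param seed Integer seed.
#' @return Data frame with `run`, the decoded factor settings, and one column
#'   per response.
#' @export
generate_ccd_responses <- function(design, truth, noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(design, "ccd_design"), is.list(truth),
            !is.null(names(truth)), noise_sigma >= 0)
  k <- ncol(design$coded)
  for (s in truth) {
    stopifnot(inherits(s, "quadratic_surface"))
    if (length(s$coefficients) != 1L + 2L * k + (k * (k - 1L)) %/% 2L) {
      stop("truth surface dimension does not match the design", call. = FALSE)
    }
  }
  out <- decode_runs(design)
  withr::with_seed(seed, {
    for (nm in names(truth)) {
      mu <- predict(truth[[nm]], design$coded)
      out[[nm]] <- mu + stats::rnorm(length(mu), 0, noise_sigma)
    }
  })
  out
}
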