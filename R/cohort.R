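# Synthetic cohort generator: per-subject ages, CSF flow metrics and fluid
# biomarkers with a configurable, known correlation structure.

#' Cohort specification
#'
#' Describes the population a synthetic cohort is drawn from. Age is uniform
#' on `age_range`. A latent pulsatility variable (on the scale of peak flow
#' rate, mm^3/s) is linear in age plus Gaussian noise; the six flow-metric
#' columns are fixed monotone linear transforms of the latent variable plus
#' small independent measurement noise, so they inter-correlate strongly, and
#' caudal flow volume is a decreasing transform (it rises with age while the
#' others fall). The CSF Ab42/40 ratio combines a direct (negative) age
#' effect with an effect of the age-residual of latent flow, so that flow and
#' the ratio remain associated after age adjustment. Null biomarkers (CSF
#' Ab42, Ab40, Ab38, pTau181, NfL, GFAP and six plasma analogues) are
#' independent of flow given age; the plasma analogues are independent of age
#' as well.
#'
#' The default noise scales are calibrated so that the population Spearman
#' correlation between age and peak flow is -0.75 and the age-adjusted
#' (partial Spearman) correlation between peak flow and the CSF Ab42/40
#' ratio is +0.70.
#'
#' @param n_subjects Number of subjects (>= 4, so the partial-correlation
#'   degrees of freedom `n - 3` are at least 1).
#' @param age_range Length-2 numeric, years; ages are uniform on this range.
#' @param flow_intercept,beta_age_flow Latent flow at age 0 (mm^3/s) and its
#'   slope on age (mm^3/s per year; negative).
#' @param sd_flow_noise SD of the latent-flow noise (the age residual).
#' @param ratio_intercept,beta_age_ratio Intercept and direct age slope of
#'   the CSF Ab42/40 ratio.
#' @param beta_flow_ratio Effect of the age-residual of latent flow on the
#'   CSF Ab42/40 ratio (per mm^3/s).
#' @param sd_ratio_noise SD of the ratio noise.
#' @param sd_metric_noise SD of the peak-flow measurement noise, mm^3/s
#'   (other metric columns use scaled versions).
#' @param seed Integer seed; generation is deterministic per seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 16, age_range = c(10, 27),
                        flow_intercept = 43, beta_age_flow = -1,
                        sd_flow_noise = 0.905 * 17 / sqrt(12),
                        ratio_intercept = 0.148, beta_age_ratio = -0.0012,
                        beta_flow_ratio = 0.0017, sd_ratio_noise = 0.00731,
                        sd_metric_noise = 0.3, seed = 1L) {
  s <- list(n_subjects = as.integer(n_subjects),
            age_range = as.numeric(age_range),
            flow_intercept = flow_intercept, beta_age_flow = beta_age_flow,
            sd_flow_noise = sd_flow_noise,
            ratio_intercept = ratio_intercept,
            beta_age_ratio = beta_age_ratio,
            beta_flow_ratio = beta_flow_ratio,
            sd_ratio_noise = sd_ratio_noise,
            sd_metric_noise = sd_metric_noise,
            seed = if (is.null(seed)) NULL else as.integer(seed))
  class(s) <- "cohort_spec"
  validate_cohort_spec(s)
  s
}

validate_cohort_spec <- function(s) {
  stopifnot(inherits(s, "cohort_spec"))
  if (s$n_subjects < 4)
    stop("n_subjects must be >= 4 (partial correlation needs df = n - 3 >= 1)")
  if (length(s$age_range) != 2 || s$age_range[1] >= s$age_range[2])
    stop("age_range must be (low, high) with low < high")
  if (s$sd_flow_noise <= 0 || s$sd_ratio_noise <= 0 || s$sd_metric_noise <= 0)
    stop("noise SDs must be > 0")
  invisible(s)
}

#' Column names of the null biomarkers
#'
#' Biomarker columns generated independently of CSF flow given age (the CSF
#' markers carry age trends; the plasma analogues are pure noise).
#' @return Character vector of column names.
#' @export
null_biomarker_columns <- function() {
  c("csf_ab42", "csf_ab40", "csf_ab38", "csf_ptau181", "csf_nfl", "csf_gfap",
    "plasma_ab42", "plasma_ab40", "plasma_ab42_40_ratio",
    "plasma_ptau181", "plasma_nfl", "plasma_gfap")
}

#' Column names of the six flow metrics
#' @return Character vector of the metric column names in a cohort table.
#' @export
flow_metric_columns <- function() {
  c("net_stroke", "cranial_volume", "caudal_volume", "absolute_stroke",
    "amplitude", "peak_flow")
}

#' Generate a synthetic cohort table
#'
#' Draws a per-subject table of age, the six CSF flow metrics and CSF/plasma
#' fluid biomarkers from the population described by a [cohort_spec].
#' Metric columns satisfy `net_stroke = cranial_volume - caudal_volume` and
#' `absolute_stroke = cranial_volume + caudal_volume` exactly.
#'
#' @param spec A [cohort_spec].
#' @return A data.frame of class `csf_cohort`, one row per subject, with
#'   columns `subject_id`, `age_years`, the six metric columns (see
#'   [flow_metric_columns()]), `csf_ab42_40_ratio` and the null biomarkers
#'   (see [null_biomarker_columns()]).
#' @examples
#' head(generate_cohort(cohort_spec(n_subjects = 16, seed = 3)))
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_subjects
  with_seed(spec$seed, {
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    eps_flow <- stats::rnorm(n, 0, spec$sd_flow_noise)
    latent <- spec$flow_intercept + spec$beta_age_flow * age + eps_flow

    sm <- spec$sd_metric_noise
    cranial <- 225 + 9.0 * (latent - 25) + stats::rnorm(n, 0, 10 * sm)
    caudal <- 90 - 3.5 * (latent - 25) + stats::rnorm(n, 0, 10 * sm)
    amplitude <- 1.6 * latent + stats::rnorm(n, 0, 5 / 3 * sm)
    peak <- latent + stats::rnorm(n, 0, sm)

    ratio <- spec$ratio_intercept + spec$beta_age_ratio * age +
      spec$beta_flow_ratio * eps_flow + stats::rnorm(n, 0, spec$sd_ratio_noise)

    tab <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      age_years = age,
      net_stroke = cranial - caudal,
      cranial_volume = cranial,
      caudal_volume = caudal,
      absolute_stroke = cranial + caudal,
      amplitude = amplitude,
      peak_flow = peak,
      csf_ab42_40_ratio = ratio,
      csf_ab42 = 850 - 18 * age + stats::rnorm(n, 0, 80),
      csf_ab40 = 7500 - 40 * age + stats::rnorm(n, 0, 600),
      csf_ab38 = 2200 + stats::rnorm(n, 0, 250),
      csf_ptau181 = 18 + 0.25 * age + stats::rnorm(n, 0, 4),
      csf_nfl = 120 + 14 * age + stats::rnorm(n, 0, 60),
      csf_gfap = 4000 + 150 * age + stats::rnorm(n, 0, 1500),
      plasma_ab42 = stats::rnorm(n, 28, 5),
      plasma_ab40 = stats::rnorm(n, 220, 30),
      plasma_ab42_40_ratio = stats::rnorm(n, 0.13, 0.02),
      plasma_ptau181 = stats::rnorm(n, 2.5, 0.6),
      plasma_nfl = stats::rnorm(n, 40, 12),
      plasma_gfap = stats::rnorm(n, 90, 25),
      stringsAsFactors = FALSE)
    class(tab) <- c("csf_cohort", "data.frame")
    tab
  })
}
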