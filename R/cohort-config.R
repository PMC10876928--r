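#' Generator settings for a synthetic screening cohort
#'
#' Defaults emulate the baseline characteristics of a two-centre Swedish
#' mammographic screening cohort with short-term incident breast cancer
#' follow-up: ~796 incident cases and ~781 median-age-matched controls over a
#' 36-month horizon, mean age at blood draw 58.5 (SD 9.6) years, mean BMI
#' 25.4 kg/m^2, ~70% postmenopausal, a mean below-LOD protein fraction of
#' 0.12 in centre A and 0.14 in centre B, and systematic per-protein NPX
#' shifts between recruitment centres.
#'
#' Protein levels follow a low-rank factor model: for protein \eqn{p},
#' \eqn{x_{ip} = \mu_p + \lambda_p' f_i + s_p(centre_i) + \epsilon_{ip}},
#' with `n_factors` latent factors per participant, loadings drawn
#' N(0, `loading_sd`), residual noise N(0, `noise_sd`) and a per-protein
#' centre-B shift with spread `batch_sd` (NPX, log2-like units). Event times
#' are proportional-hazards Weibull (exponential for `weibull_shape = 1`)
#' with log-hazard \eqn{\sum_p \beta_p z_{ip} + } covariate effects, where
#' \eqn{z_{ip}} is the protein in per-SD units; administrative censoring at
#' `horizon` months.
#'
#' @param n_cases,n_controls target numbers of incident cases and matched
#'   controls in the returned sample.
#' @param centres recruitment centres present; `c("A", "B")` for the
#'   two-centre targeted design, `"B"` for a single-centre design.
#' @param centre_a_frac fraction of participants recruited in centre A when
#'   both centres are present.
#' @param age_mean,age_sd age at blood draw (years).
#' @param bmi_mean,bmi_sd body mass index (kg/m^2).
#' @param menopause_age_mean,menopause_age_sd latent age at menopause used to
#'   derive postmenopausal status from age (gives ~70% postmenopausal at the
#'   default age distribution).
#' @param p_smoker,p_lipid_med,p_heart_med,p_renal_failure,p_family_history
#'   Bernoulli prevalences of the binary covariates.
#' @param density_shape1,density_shape2 Beta parameters for percent
#'   mammographic density (fraction in [0,1], mean 0.25 by default).
#' @param plasma_age_mean,plasma_age_sd plasma storage age (years).
#' @param grs_mean,grs_sd polygenic risk score distribution (unitless).
#' @param n_proteins,n_factors,loading_sd,noise_sd factor-model dimensions
#'   and scales (NPX units).
#' @param npx_level_range range of per-protein mean NPX levels (uniform).
#' @param batch_sd SD of the per-protein additive centre-B shift (NPX).
#' @param lod_quantile named per-centre target mean below-LOD fraction.
#' @param missing_rate missing-completely-at-random rate per centre; scalar
#'   or named vector `c(A = , B = )`.
#' @param p_qc_warning per-protein probability of a vendor-style QC warning.
#' @param panel_mode `"targeted"` (proteins split over CAM/IMONC panel
#'   labels) or `"exploratory"`.
#' @param horizon administrative censoring horizon in months.
#' @param time_resolution `"month"` (event/censoring times rounded up to
#'   whole months) or `"continuous"`.
#' @param oversample pool inflation factor: the generator simulates
#'   `oversample * (n_cases + n_controls)` women and calibrates the baseline
#'   hazard so expected events are `oversample * n_cases`; cases and
#'   controls are then kept at the same rate `1/oversample`, making the
#'   retained case-control sample a near-equal-rate random subsample of the
#'   pool (which keeps the Cox fit on the sample essentially unbiased). The
#'   default 1.3 also leaves enough non-case slack for median age matching
#'   when case ages run above the population mean.
#' @param baseline_hazard per-month baseline rate; `NULL` (default)
#'   calibrates it at generation time by root finding.
#' @param weibull_shape Weibull shape of the event-time model; 1 gives the
#'   default exponential.
#' @param p_er_positive,p_node_positive,p_high_grade,p_interval tumour-marker
#'   and mode-of-detection frequencies among cases.
#' @param match_tolerance tolerance (years) for median age matching.
#' @param effects an [effect_spec()] with true protein and covariate
#'   log hazard ratios.
#' @return an object of class `cohort_config` (a named list).
#' @seealso [generate_cohort()], [effect_spec()]
#' @export
#' @examples
#' cfg <- cohort_config(n_cases = 50, n_controls = 50, n_proteins = 10)
#' sim <- generate_cohort(cfg, seed = 1)
cohort_config <- function(n_cases = 796,
                          n_controls = 781,
                          centres = c("A", "B"),
                          centre_a_frac = 0.517,
                          age_mean = 58.5, age_sd = 9.6,
                          bmi_mean = 25.4, bmi_sd = 4.2,
                          menopause_age_mean = 53, menopause_age_sd = 4,
                          p_smoker = 0.56,
                          p_lipid_med = 0.128,
                          p_heart_med = 0.11,
                          p_renal_failure = 0.004,
                          p_family_history = 0.13,
                          density_shape1 = 1.8, density_shape2 = 5.4,
                          plasma_age_mean = 7.8, plasma_age_sd = 0.7,
                          grs_mean = -0.05, grs_sd = 0.30,
                          n_proteins = 163,
                          n_factors = 5,
                          loading_sd = 0.2,
                          noise_sd = 0.5,
                          npx_level_range = c(1, 10),
                          batch_sd = 0.5,
                          lod_quantile = c(A = 0.12, B = 0.14),
                          missing_rate = 0.02,
                          p_qc_warning = 0,
                          panel_mode = c("targeted", "exploratory"),
                          horizon = 36,
                          time_resolution = c("month", "continuous"),
                          oversample = 1.30,
                          baseline_hazard = NULL,
                          weibull_shape = 1,
                          p_er_positive = 0.85,
                          p_node_positive = 0.30,
                          p_high_grade = 0.25,
                          p_interval = 0.30,
                          match_tolerance = 0.5,
                          effects = effect_spec()) {
  panel_mode <- match.arg(panel_mode)
  time_resolution <- match.arg(time_resolution)
  centres <- match.arg(centres, c("A", "B"), several.ok = TRUE)
  if (n_cases < 1 || n_controls < 1)
    stop_protscan("n_cases and n_controls must both be >= 1 (got %s, %s)",
                  n_cases, n_controls)
  if (n_proteins < 1) stop_protscan("n_proteins must be >= 1")
  if (horizon <= 0) stop_protscan("horizon must be positive")
  if (oversample <= 1) stop_protscan("oversample must exceed 1")
  if (!inherits(effects, "effect_spec"))
    stop_protscan("`effects` must be created with effect_spec()")
  cfg <- as.list(environment())
  structure(cfg, class = "cohort_config")
}

#' True effect sizes for the synthetic event-time model
#'
#' Protein effects are log hazard ratios per SD of protein level; proteins
#' not named have a true effect of zero (the global null). Covariate effects
#' are log hazard ratios on the covariate's natural scale (per year of age,
#' per kg/m^2 of BMI, per unit of the risk score, per unit fraction of
#' percent density, per level of a binary indicator).
#'
#' @param proteins named numeric vector of per-SD log hazard ratios, names
#'   matching generated protein ids (e.g. `"P0001"`); `NULL` for the global
#'   null.
#' @param age,bmi,postmenopausal,ever_smoked,lipid_med,heart_med,
#'   renal_failure,family_history,percent_density,plasma_age,grs covariate
#'   log hazard ratios.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(proteins = NULL,
                        age = 0.003,
                        bmi = 0.015,
                        postmenopausal = 0.05,
                        ever_smoked = 0.05,
                        lipid_med = 0,
                        heart_med = 0,
                        renal_failure = 0,
                        family_history = 0.45,
                        percent_density = 1.2,
                        plasma_age = 0,
                        grs = 1.5) {
  if (!is.null(proteins)) {
    if (is.null(names(proteins)) || any(!nzchar(names(proteins))))
      stop_protscan("protein effects must be a named numeric vector")
    if (any(!is.finite(proteins)))
      stop_protscan("protein effects must be finite")
  }
  covars <- c(age = age, bmi = bmi, postmenopausal = postmenopausal,
              ever_smoked = ever_smoked, lipid_med = lipid_med,
              heart_med = heart_med, renal_failure = renal_failure,
              family_history = family_history,
              percent_density = percent_density,
              plasma_age = plasma_age, grs = grs)
  if (any(!is.finite(covars))) stop_protscan("covariate effects must be finite")
  structure(list(proteins = proteins, covariates = covars),
            class = "effect_spec")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  target sample : %d cases / %d controls, centres %s\n",
              x$n_cases, x$n_controls, paste(x$centres, collapse = "+")))
  cat(sprintf("  proteins      : %d (%s panel), %d latent factors\n",
              x$n_proteins, x$panel_mode, x$n_factors))
  cat(sprintf("  follow-up     : %d months, %s resolution\n",
              x$horizon, x$time_resolution))
  n_eff <- length(x$effects$proteins)
  cat(sprintf("  true effects  : %d protein(s) non-null\n", n_eff))
  invisible(x)
}
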