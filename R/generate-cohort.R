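#' Generate a synthetic screening cohort with an NPX protein panel
#'
#' Simulates a pool of `oversample * (n_cases + n_controls)` women with
#' covariates drawn from the configured distributions, protein levels from a
#' low-rank factor model with centre-specific additive shifts, and
#' proportional-hazards event times with administrative censoring at the
#' horizon. Women with an event inside the horizon are incident cases; the
#' returned sample keeps `n_cases` randomly chosen cases plus `n_controls`
#' non-cases selected by median matching on age at blood draw. Per-protein detection limits are placed at the
#' quantile that yields the configured mean below-LOD fraction per centre,
#' and missingness is applied completely at random per centre.
#'
#' The master seed drives a hierarchy of derived streams (covariates,
#' factor scores, one stream per protein, event draws, selection, matching,
#' tumour markers), so output is bit-reproducible and adding proteins does
#' not perturb earlier streams.
#'
#' @param config a [cohort_config()].
#' @param seed integer master seed.
#' @return object of class `sim_cohort`: a list with elements `cohort`
#'   (participant data.frame, see [write_cohort()] for the column
#'   dictionary), `npx` (an [npx_matrix()] for the retained samples),
#'   `baseline_hazard` (per-month rate actually used), `achieved_events`
#'   (event count in the pool), `config`, `seed`.
#' @export
#' @examples
#' sim <- generate_cohort(cohort_config(n_cases = 40, n_controls = 40,
#'                                      n_proteins = 8), seed = 7)
#' sim
#' table(sim$cohort$is_case)
generate_cohort <- function(config, seed) {
  if (!inherits(config, "cohort_config"))
    stop_protscan("`config` must be created with cohort_config()")
  if (missing(seed) || !is.finite(seed))
    stop_protscan("an integer `seed` is required")
  cfg <- config
  n_target <- cfg$n_cases + cfg$n_controls
  n_pool <- ceiling(cfg$oversample * n_target)
  protein_ids <- sprintf("P%04d", seq_len(cfg$n_proteins))
  eff <- cfg$effects
  if (!is.null(eff$proteins)) {
    unknown <- setdiff(names(eff$proteins), protein_ids)
    if (length(unknown))
      stop_protscan("effect spec references unknown protein(s): %s",
                    paste(unknown, collapse = ", "))
  }

  ## -- covariates -----------------------------------------------------------
  set.seed(derive_seed(seed, "covariates"))
  centre <- if (length(cfg$centres) == 1L) rep(cfg$centres, n_pool) else
    sample(c("A", "B"), n_pool, replace = TRUE,
           prob = c(cfg$centre_a_frac, 1 - cfg$centre_a_frac))
  age <- rnorm_trunc(n_pool, cfg$age_mean, cfg$age_sd, 30, 90)
  bmi <- rnorm_trunc(n_pool, cfg$bmi_mean, cfg$bmi_sd, 15, 55)
  menop_age <- stats::rnorm(n_pool, cfg$menopause_age_mean,
                            cfg$menopause_age_sd)
  postmenopausal <- age >= menop_age
  ever_smoked <- stats::runif(n_pool) < cfg$p_smoker
  lipid_med <- stats::runif(n_pool) < cfg$p_lipid_med
  heart_med <- stats::runif(n_pool) < cfg$p_heart_med
  renal_failure <- stats::runif(n_pool) < cfg$p_renal_failure
  family_history <- stats::runif(n_pool) < cfg$p_family_history
  percent_density <- stats::rbeta(n_pool, cfg$density_shape1,
                                  cfg$density_shape2)
  plasma_age <- rnorm_trunc(n_pool, cfg$plasma_age_mean, cfg$plasma_age_sd,
                            0.5, Inf)
  grs <- stats::rnorm(n_pool, cfg$grs_mean, cfg$grs_sd)

  ## -- proteins: latent factors + per-protein streams -----------------------
  set.seed(derive_seed(seed, "factors"))
  fscores <- matrix(stats::rnorm(n_pool * cfg$n_factors), n_pool,
                    cfg$n_factors)
  values <- matrix(NA_real_, n_pool, cfg$n_proteins)
  miss_u <- matrix(NA_real_, n_pool, cfg$n_proteins)
  mu <- raw_shift <- s_tot <- numeric(cfg$n_proteins)
  for (p in seq_len(cfg$n_proteins)) {
    set.seed(derive_seed(seed, "protein", p))
    mu[p] <- stats::runif(1, cfg$npx_level_range[1], cfg$npx_level_range[2])
    loadings <- stats::rnorm(cfg$n_factors, 0, cfg$loading_sd)
    raw_shift[p] <- stats::rnorm(1, 0, cfg$batch_sd)
    noise <- stats::rnorm(n_pool, 0, cfg$noise_sd)
    miss_u[, p] <- stats::runif(n_pool)
    s_tot[p] <- sqrt(sum(loadings^2) + cfg$noise_sd^2)
    values[, p] <- mu[p] + drop(fscores %*% loadings) + noise
  }

  ## -- centre shifts and detection limits -----------------------------------
  ## Centre A is the LOD reference; a global offset on the centre-B shifts is
  ## solved so the mean below-LOD probability in centre B hits its target.
  q_a <- unname(cfg$lod_quantile["A"])
  q_b <- unname(cfg$lod_quantile["B"])
  two_centre <- length(cfg$centres) == 2L
  if (two_centre) {
    z_a <- stats::qnorm(q_a)
    gap <- function(off)
      mean(stats::pnorm(z_a - (raw_shift + off) / s_tot)) - q_b
    off <- stats::uniroot(gap, c(-5, 5), tol = 1e-10)$root
    shift_b <- raw_shift + off
    lod <- mu + z_a * s_tot
  } else {
    q_ref <- if (cfg$centres == "A") q_a else q_b
    shift_b <- rep(0, cfg$n_proteins)
    lod <- mu + stats::qnorm(q_ref) * s_tot
  }

  ## -- event times under proportional hazards -------------------------------
  ## Hazards act on the biological signal (pre batch shift): the centre
  ## shift is a technical artefact of measurement, not of risk, and the
  ## per-centre normalization downstream removes it from the exposure.
  z <- scale(values)
  if (two_centre) {
    is_b <- centre == "B"
    values[is_b, ] <- values[is_b, , drop = FALSE] +
      matrix(shift_b, sum(is_b), cfg$n_proteins, byrow = TRUE)
  }
  eta <- drop(z %*% protein_beta(eff, protein_ids))
  cv <- eff$covariates
  eta <- eta +
    cv["age"] * (age - cfg$age_mean) +
    cv["bmi"] * (bmi - cfg$bmi_mean) +
    cv["postmenopausal"] * postmenopausal +
    cv["ever_smoked"] * ever_smoked +
    cv["lipid_med"] * lipid_med +
    cv["heart_med"] * heart_med +
    cv["renal_failure"] * renal_failure +
    cv["family_history"] * family_history +
    cv["percent_density"] * (percent_density - 0.25) +
    cv["plasma_age"] * (plasma_age - cfg$plasma_age_mean) +
    cv["grs"] * (grs - cfg$grs_mean)
  eta <- unname(eta)

  set.seed(derive_seed(seed, "events"))
  e_std <- stats::rexp(n_pool)
  shape <- cfg$weibull_shape
  expected_events <- function(l0)
    sum(1 - exp(-l0 * cfg$horizon^shape * exp(eta)))
  if (is.null(cfg$baseline_hazard)) {
    target <- min(cfg$oversample * cfg$n_cases, 0.98 * n_pool)
    l0 <- stats::uniroot(function(l) expected_events(l) - target,
                         lower = 1e-12, upper = 1e3, tol = 1e-12)$root
  } else l0 <- cfg$baseline_hazard
  t_event <- (e_std / (l0 * exp(eta)))^(1 / shape)
  event <- t_event <= cfg$horizon
  time <- pmin(t_event, cfg$horizon)
  if (cfg$time_resolution == "month") time <- ceiling(time)
  achieved <- sum(event)
  if (achieved < cfg$n_cases)
    stop_protscan(paste0("requested %d cases but only %d events achieved ",
                         "(event fraction %.3f) at baseline hazard %.3g; ",
                         "raise baseline_hazard or oversample"),
                  cfg$n_cases, achieved, achieved / n_pool, l0)
  if (n_pool - achieved < cfg$n_controls)
    stop_protscan("only %d non-cases available for %d requested controls",
                  n_pool - achieved, cfg$n_controls)

  ## -- case selection and median-matched controls ---------------------------
  set.seed(derive_seed(seed, "select"))
  case_idx <- sort(sample(which(event), cfg$n_cases))
  pool <- data.frame(idx = seq_len(n_pool), age_at_draw = age,
                     is_case = FALSE)
  pool$is_case[case_idx] <- TRUE
  pool <- pool[pool$is_case | !event, ]  # drop surplus cases entirely
  ## short rejection budget here: with age-shifted cases a uniform draw
  ## rarely lands within tolerance and the greedy fallback is cheap
  ctrl_rows <- match_controls(pool, cfg$n_controls,
                              variable = "age_at_draw",
                              tolerance = cfg$match_tolerance,
                              seed = derive_seed(seed, "match"),
                              id_col = "idx", max_draws = 200)
  keep <- sort(c(case_idx, ctrl_rows))
  is_case <- keep %in% case_idx

  ## -- tumour markers and detection mode (cases only) -----------------------
  set.seed(derive_seed(seed, "tumour"))
  n_case <- length(case_idx)
  detection <- ifelse(stats::runif(n_case) < cfg$p_interval,
                      "interval", "screen_detected")
  er_pos <- stats::runif(n_case) < cfg$p_er_positive
  node_pos <- stats::runif(n_case) < cfg$p_node_positive
  high_grade <- stats::runif(n_case) < cfg$p_high_grade

  ## -- assemble outputs ------------------------------------------------------
  sample_ids <- sprintf("S%05d", keep)
  v <- values[keep, , drop = FALSE]
  v[miss_u[keep, , drop = FALSE] < missing_rate_for(cfg, centre[keep])] <- NA
  dimnames(v) <- list(sample_ids, protein_ids)
  panel <- if (cfg$panel_mode == "exploratory") rep("exploratory",
                                                    cfg$n_proteins) else
    rep(c("targeted_CAM", "targeted_IMONC"),
        c(ceiling(cfg$n_proteins / 2), floor(cfg$n_proteins / 2)))
  set.seed(derive_seed(seed, "qcflags"))
  qc_warn <- stats::runif(cfg$n_proteins) < cfg$p_qc_warning
  npx <- npx_matrix(v, lod, panel, qc_warn)

  cohort <- data.frame(
    id = sample_ids,
    centre = centre[keep],
    age_at_draw = age[keep],
    bmi = bmi[keep],
    postmenopausal = postmenopausal[keep],
    ever_smoked = ever_smoked[keep],
    lipid_med = lipid_med[keep],
    heart_med = heart_med[keep],
    renal_failure = renal_failure[keep],
    family_history = family_history[keep],
    percent_density = percent_density[keep],
    grs = grs[keep],
    plasma_age = plasma_age[keep],
    pct_below_lod = pct_below_lod_safe(npx),
    is_case = is_case,
    time = ifelse(is_case, time[keep], cfg$horizon),
    event = is_case,
    detection_mode = NA_character_,
    er_positive = NA, node_positive = NA, high_grade = NA,
    stringsAsFactors = FALSE)
  case_pos <- match(case_idx, keep)
  cohort$detection_mode[case_pos] <- detection
  cohort$er_positive[case_pos] <- er_pos
  cohort$node_positive[case_pos] <- node_pos
  cohort$high_grade[case_pos] <- high_grade
  rownames(cohort) <- NULL

  structure(list(cohort = cohort, npx = npx, baseline_hazard = l0,
                 achieved_events = achieved, config = cfg, seed = seed),
            class = "sim_cohort")
}

# As pct_below_lod() but tolerant: a sample with no non-missing protein
# gets NA (it is then excluded by complete-case analysis downstream).
pct_below_lod_safe <- function(npx) {
  v <- npx$values
  n_obs <- rowSums(!is.na(v))
  out <- rowSums(sweep(v, 2, npx$lod, "<"), na.rm = TRUE) / n_obs
  out[n_obs == 0] <- NA_real_
  out
}

protein_beta <- function(eff, protein_ids) {
  beta <- stats::setNames(rep(0, length(protein_ids)), protein_ids)
  if (!is.null(eff$proteins)) beta[names(eff$proteins)] <- eff$proteins
  beta
}

missing_rate_for <- function(cfg, centre) {
  r <- cfg$missing_rate
  if (length(r) == 1L) return(rep(unname(r), length(centre)))
  unname(r[centre])
}

#' @export
print.sim_cohort <- function(x, ...) {
  co <- x$cohort
  cat(sprintf("Simulated cohort: %d cases / %d controls, %d proteins\n",
              sum(co$is_case), sum(!co$is_case), ncol(x$npx$values)))
  cat(sprintf("  median age cases %.1f / controls %.1f; baseline hazard %.3g/month\n",
              stats::median(co$age_at_draw[co$is_case]),
              stats::median(co$age_at_draw[!co$is_case]),
              x$baseline_hazard))
  invisible(x)
}

#' Sum weighted risk-allele dosages into a polygenic risk score
#'
#' The score for individual i is the sum over variants of the allele dosage
#' (0, 1 or 2 risk alleles) multiplied by the variant's log odds ratio;
#' higher scores mean higher modelled risk.
#'
#' @param dosages integer matrix (individuals x variants) with entries in
#'   \{0, 1, 2\}; a vector is treated as one individual.
#' @param weights numeric vector of per-variant log odds ratios; if named
#'   and `dosages` has column names, variants are aligned by name.
#' @return numeric vector of per-individual scores.
#' @export
#' @examples
#' compute_grs(c(0, 1, 2), c(0.1, -0.2, 0.3))  # 0.4
compute_grs <- function(dosages, weights) {
  if (is.null(dim(dosages))) dosages <- matrix(dosages, nrow = 1)
  if (!all(dosages %in% c(0, 1, 2)))
    stop_protscan("dosages must be allele counts in {0, 1, 2}")
  if (!all(is.finite(weights))) stop_protscan("weights must be finite")
  if (!is.null(names(weights)) && !is.null(colnames(dosages))) {
    if (!setequal(names(weights), colnames(dosages)))
      stop_protscan("dosage columns and weight names do not match")
    weights <- weights[colnames(dosages)]
  }
  if (ncol(dosages) != length(weights))
    stop_protscan("dosage matrix has %d variants but %d weights supplied",
                  ncol(dosages), length(weights))
  drop(dosages %*% weights)
}

#' Select controls by median matching on a covariate
#'
#' Draws candidate control sets uniformly at random from the non-cases and
#' accepts the first whose median of `variable` lies within `tolerance` of
#' the case median (rejection sampling, budget `max_draws`). If the budget
#' is exhausted, a greedy pass swaps selected controls for unused candidates
#' on the deficient side of the target until the tolerance is met.
#'
#' @param cohort data.frame with a logical `is_case` column, the matching
#'   variable and an id column.
#' @param n_controls number of controls to select.
#' @param variable matching covariate name (default `"age_at_draw"`).
#' @param tolerance maximal allowed |control median - case median| in the
#'   variable's units (default 0.5 years).
#' @param seed integer seed; selection is randomized among valid sets.
#' @param id_col column returned as identifier (default `"id"`).
#' @param max_draws rejection-sampling budget.
#' @return vector of selected control ids.
#' @export
match_controls <- function(cohort, n_controls, variable = "age_at_draw",
                           tolerance = 0.5, seed, id_col = "id",
                           max_draws = 10000) {
  if (!variable %in% names(cohort))
    stop_protscan("matching variable '%s' not found in cohort", variable)
  cand <- cohort[!cohort$is_case, , drop = FALSE]
  if (anyNA(cand[[variable]]))
    stop_protscan("matching variable has missing values among candidates")
  if (nrow(cand) < n_controls)
    stop_protscan("only %d candidate controls for %d requested",
                  nrow(cand), n_controls)
  target <- stats::median(cohort[[variable]][cohort$is_case])
  x <- cand[[variable]]
  set.seed(seed)
  best <- NULL
  best_gap <- Inf
  for (i in seq_len(max_draws)) {
    idx <- sample.int(nrow(cand), n_controls)
    gap <- abs(stats::median(x[idx]) - target)
    if (gap < best_gap) {
      best <- idx
      best_gap <- gap
    }
    if (gap <= tolerance) return(cand[[id_col]][idx])
  }
  ## greedy fallback: trade a control from the heavy side for an unused
  ## candidate on the light side, moving the median toward the target
  ## while leaving the rest of the random draw intact
  refined <- greedy_median_swap(best, x, target, tolerance)
  if (abs(stats::median(x[refined]) - target) <= tolerance)
    return(cand[[id_col]][refined])
  ## last resort for small or skewed pools: the achievable medians of an
  ## n_controls-subset are the medians of windows of the sorted candidates;
  ## restart the greedy pass from the window whose median is closest
  ord <- order(x)
  n_win <- nrow(cand) - n_controls + 1
  win_med <- vapply(seq_len(n_win), function(i)
    stats::median(x[ord[i:(i + n_controls - 1)]]), numeric(1))
  i_best <- which.min(abs(win_med - target))
  windowed <- greedy_median_swap(ord[i_best:(i_best + n_controls - 1)],
                                 x, target, tolerance)
  gap <- abs(stats::median(x[windowed]) - target)
  if (gap <= tolerance) return(cand[[id_col]][windowed])
  stop_protscan(paste0("median matching failed: best achieved gap %.3f ",
                       "exceeds tolerance %.3f"),
                min(gap, best_gap, abs(stats::median(x[refined]) - target)),
                tolerance)
}

greedy_median_swap <- function(idx, x, target, tolerance) {
  for (i in seq_along(x)) {
    med <- stats::median(x[idx])
    if (abs(med - target) <= tolerance) return(idx)
    unused <- setdiff(seq_along(x), idx)
    if (med < target) {
      out <- idx[which.min(x[idx])]
      into <- unused[x[unused] > med]
    } else {
      out <- idx[which.max(x[idx])]
      into <- unused[x[unused] < med]
    }
    if (!length(into)) break
    into <- into[which.min(abs(x[into] - target))]
    idx <- c(setdiff(idx, out), into)
  }
  idx
}
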