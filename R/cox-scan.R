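#' Default covariate adjustment set for the association scans
#'
#' The adjustment set used throughout: age at blood draw, BMI, lipid and
#' heart medication, renal failure, smoking status, menopause status,
#' family history, percent mammographic density, age of plasma, per-sample
#' below-LOD fraction and the polygenic risk score. Recruitment centre is
#' appended by the scan itself when more than one centre is present.
#'
#' @return character vector of cohort column names.
#' @export
adjustment_set <- function() {
  c("age_at_draw", "bmi", "lipid_med", "heart_med", "renal_failure",
    "ever_smoked", "postmenopausal", "family_history", "percent_density",
    "plasma_age", "pct_below_lod", "grs")
}

# A coxph warning concerns the record only if it signals global
# non-convergence or an infinite coefficient for the exposure itself (the
# first model term); a diverging nuisance covariate (e.g. a rare binary
# indicator with no events in one level) leaves the exposure's Wald
# inference intact and is not flagged.
exposure_convergence_warning <- function(msg) {
  if (grepl("Ran out of iterations", msg)) return(TRUE)
  if (grepl("variable\\s+[0-9]+", msg)) {
    var_no <- as.integer(sub(".*variable\\s+([0-9]+).*", "\\1", msg))
    return(identical(var_no, 1L))
  }
  grepl("converge|infinite", msg)
}

# Assemble the adjustment covariates from a cohort table. Logicals become
# 0/1; recruitment centre enters as a factor iff more than one centre is
# present among the analyzed samples.
scan_covariates <- function(cohort, adjustment = adjustment_set()) {
  missing_cov <- setdiff(adjustment, names(cohort))
  if (length(missing_cov))
    stop_protscan("cohort table lacks adjustment covariate(s): %s",
                  paste(missing_cov, collapse = ", "))
  covars <- cohort[, adjustment, drop = FALSE]
  covars[] <- lapply(covars, function(x) if (is.logical(x)) as.numeric(x)
                     else x)
  if (length(unique(cohort$centre)) > 1)
    covars$centre <- factor(cohort$centre)
  covars
}

#' Covariate-adjusted Cox proportional-hazards fit for one exposure
#'
#' Fits `Surv(time, event) ~ exposure + covariates` by partial-likelihood
#' maximization (Efron tie handling by default, suited to the monthly time
#' resolution of the synthetic cohorts) on complete cases. The exposure is
#' standardized to unit SD among the analyzed samples first, so the
#' returned coefficient is a log hazard ratio per SD of exposure.
#'
#' @param exposure numeric vector of per-sample exposure values.
#' @param covariates data.frame of adjustment covariates, or `NULL`.
#' @param time follow-up time in months.
#' @param event logical event indicator.
#' @param ties `"efron"` or `"breslow"`.
#' @param id label recorded in the output (default `"exposure"`).
#' @param min_events minimal number of events required among complete cases
#'   (default 10); lower it only for didactic toy fits.
#' @return one-row data.frame (an association record): `protein`, `beta`
#'   (log HR per SD), `se`, `hr`, `p` (two-sided Wald), `n_used`,
#'   `n_events`, `flag` (`""`, `"nonconvergence"` or `"separation"`).
#' @export
fit_cox <- function(exposure, covariates = NULL, time, event,
                    ties = c("efron", "breslow"), id = "exposure",
                    min_events = 10) {
  ties <- match.arg(ties)
  n <- length(exposure)
  stopifnot(length(time) == n, length(event) == n)
  cc <- !is.na(exposure) & !is.na(time) & !is.na(event)
  if (!is.null(covariates)) cc <- cc & stats::complete.cases(covariates)
  if (sum(event[cc]) < min_events)
    stop_protscan("fewer than %d events among complete cases for %s",
                  min_events, id)
  x <- exposure[cc]
  sdx <- stats::sd(x)
  if (!is.finite(sdx) || sdx == 0)
    stop_protscan("exposure %s has zero variance among complete cases", id)
  dat <- data.frame(.time = time[cc], .event = event[cc],
                    .x = (x - mean(x)) / sdx)
  if (!is.null(covariates)) dat <- cbind(dat, covariates[cc, , drop = FALSE])
  flag <- ""
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                    ties = ties,
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 100)),
    warning = function(w) {
      if (exposure_convergence_warning(conditionMessage(w)))
        flag <<- "nonconvergence"
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit)[".x"])
  se <- sqrt(diag(stats::vcov(fit))[".x"])
  if (is.finite(beta) && abs(beta) > 20) flag <- "separation"
  p <- 2 * stats::pnorm(-abs(beta / se))
  data.frame(protein = id, beta = beta, se = unname(se), hr = exp(beta),
             p = unname(p), n_used = sum(cc), n_events = sum(event[cc]),
             flag = flag, stringsAsFactors = FALSE)
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni: `min(1, m * p)`. Benjamini-Hochberg: step-up with the
#' cumulative-minimum monotonicity enforcement, controlling the false
#' discovery rate.
#'
#' @param p numeric p-values in (0, 1].
#' @param method `"bonferroni"` or `"bh_fdr"`.
#' @return adjusted values, same order as input.
#' @export
#' @examples
#' adjust_multiplicity(c(0.01, 0.02, 0.04), "bh_fdr")  # 0.03 0.03 0.04
adjust_multiplicity <- function(p, method = c("bonferroni", "bh_fdr")) {
  method <- match.arg(method)
  if (!length(p)) stop_protscan("empty p-value vector")
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop_protscan("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = c(bonferroni = "bonferroni",
                                bh_fdr = "BH")[[method]])
}

#' Per-protein Cox association scan
#'
#' Runs [fit_cox()] for every protein of a normalized matrix (and
#' optionally for principal-component exposures), attaches Bonferroni and
#' FDR adjusted p-values and significance flags, and sorts by p. The
#' multiplicity family size m is the number of proteins scanned; PC
#' exposures form their own separate family.
#'
#' @param matrix normalized samples x proteins matrix (e.g. from
#'   [inverse_normal_transform()]); rownames must be cohort ids.
#' @param cohort cohort data.frame with the outcome (`time`, `event`) and
#'   adjustment covariates.
#' @param adjustment character vector of covariate names (default
#'   [adjustment_set()]); recruitment centre is added automatically when
#'   both centres are present.
#' @param pc_scores optional samples x k PC score matrix tested as
#'   additional exposures.
#' @param alpha nominal significance level for the attached flags.
#' @param ties tie handling passed to [fit_cox()].
#' @return a `protein_scan`: data.frame with one association record per
#'   exposure (`protein`, `beta`, `se`, `hr`, `p`, `p_bonferroni`,
#'   `q_fdr`, `n_used`, `n_events`, `flag`, `family`, `nominal`,
#'   `bonferroni_sig`, `fdr_sig`), sorted by p within family.
#' @export
run_scan <- function(matrix, cohort, adjustment = adjustment_set(),
                     pc_scores = NULL, alpha = 0.05,
                     ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  v <- unclass(matrix)
  ids <- rownames(v)
  if (is.null(ids) || !all(ids %in% cohort$id))
    stop_protscan("matrix samples are not all present in the cohort table")
  co <- cohort[match(ids, cohort$id), ]
  covars <- scan_covariates(co, adjustment)

  ## the per-protein fits go through survival's fitting routine directly,
  ## with the covariate design matrix built once: identical estimates to
  ## fit_cox() at a fraction of the per-fit formula overhead
  mm <- if (ncol(covars)) stats::model.matrix(~ ., data = covars)[, -1,
                                                                  drop = FALSE]
    else NULL
  cc_base <- stats::complete.cases(covars) & !is.na(co$time) &
    !is.na(co$event)
  ctrl <- survival::coxph.control(eps = 1e-10, iter.max = 100)
  fit_one <- function(x, pid) {
    cc <- cc_base & !is.na(x)
    if (sum(co$event[cc]) < 10)
      stop_protscan("fewer than 10 events among complete cases for %s", pid)
    xs <- x[cc]
    sdx <- stats::sd(xs)
    if (!is.finite(sdx) || sdx == 0)
      stop_protscan("exposure %s has zero variance among complete cases",
                    pid)
    xs <- (xs - mean(xs)) / sdx
    xmat <- cbind(.x = xs, mm[cc, , drop = FALSE])
    y <- survival::Surv(co$time[cc], co$event[cc])
    flag <- ""
    f <- withCallingHandlers(
      survival::coxph.fit(xmat, y, strata = NULL, offset = NULL,
                          init = NULL, control = ctrl, weights = NULL,
                          method = ties, rownames = NULL),
      warning = function(w) {
        if (exposure_convergence_warning(conditionMessage(w)))
          flag <<- "nonconvergence"
        invokeRestart("muffleWarning")
      })
    beta <- unname(f$coefficients[1])
    se <- sqrt(f$var[1, 1])
    if (!is.finite(beta) || f$iter >= ctrl$iter.max) flag <- "nonconvergence"
    else if (abs(beta) > 20) flag <- "separation"
    data.frame(protein = pid, beta = beta, se = se, hr = exp(beta),
               p = 2 * stats::pnorm(-abs(beta / se)), n_used = sum(cc),
               n_events = sum(co$event[cc]), flag = flag,
               stringsAsFactors = FALSE)
  }
  scan_block <- function(mat, family) {
    recs <- lapply(colnames(mat), function(pid) fit_one(mat[, pid], pid))
    recs <- do.call(rbind, recs)
    m <- nrow(recs)
    recs$p_bonferroni <- adjust_multiplicity(recs$p, "bonferroni")
    recs$q_fdr <- adjust_multiplicity(recs$p, "bh_fdr")
    recs$family <- family
    recs$nominal <- recs$p < alpha
    recs$bonferroni_sig <- recs$p < alpha / m
    recs$fdr_sig <- recs$q_fdr < alpha
    recs[order(recs$p), ]
  }
  out <- scan_block(v, "protein")
  m_prot <- nrow(out)
  if (!is.null(pc_scores)) {
    pcs <- as.matrix(pc_scores)
    if (is.null(colnames(pcs))) colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    out <- rbind(out, scan_block(pcs[ids, , drop = FALSE], "pc"))
  }
  rownames(out) <- NULL
  structure(out, class = c("protein_scan", "data.frame"),
            m = m_prot, alpha = alpha)
}

#' @export
print.protein_scan <- function(x, n = 10, ...) {
  m <- attr(x, "m")
  alpha <- attr(x, "alpha")
  prot <- x[x$family == "protein", ]
  cat(sprintf("Protein association scan: %d proteins, %d events\n",
              m, max(prot$n_events)))
  cat(sprintf("  nominal (p < %.2g): %d   Bonferroni (p < %.2g/%d): %d   FDR (q < %.2g): %d\n",
              alpha, sum(prot$nominal), alpha, m, sum(prot$bonferroni_sig),
              alpha, sum(prot$fdr_sig)))
  print(utils::head(as.data.frame(prot)[, c("protein", "beta", "se", "hr",
                                            "p", "p_bonferroni", "q_fdr")],
                    n), digits = 3)
  invisible(x)
}

#' @export
summary.protein_scan <- function(object, ...) {
  prot <- object[object$family == "protein", ]
  list(m = attr(object, "m"),
       n_nominal = sum(prot$nominal),
       n_bonferroni = sum(prot$bonferroni_sig),
       n_fdr = sum(prot$fdr_sig),
       top = utils::head(prot, 5),
       mean_abs_beta_nominal = if (any(prot$nominal))
         mean(abs(prot$beta[prot$nominal])) else NA_real_)
}

#' Write an association table as TSV
#' @param scan a `protein_scan`
#' @param path output file
#' @export
write_scan <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subtype-stratified association scans
#'
#' Re-runs the scan with all controls retained and cases restricted by a
#' tumour-characteristic rule: oestrogen-receptor status (`"er"`), nodal
#' status (`"node"`), grade (`"grade"`), mode of detection
#' (`"detection"`), or time from blood draw to diagnosis split at the case
#' median (`"time_median"`). Strata with fewer than 10 case events are
#' skipped and reported.
#'
#' @param matrix,cohort,adjustment,pc_scores,alpha,ties as in [run_scan()].
#' @param stratum one of the rule names above.
#' @return list with one `protein_scan` per stratum plus a `skipped`
#'   data.frame naming strata with too few case events.
#' @export
stratified_scan <- function(matrix, cohort, stratum = c("er", "node",
                                                        "grade", "detection",
                                                        "time_median"),
                            adjustment = adjustment_set(), pc_scores = NULL,
                            alpha = 0.05, ties = "efron") {
  stratum <- match.arg(stratum)
  case <- cohort$is_case
  rules <- switch(stratum,
    er = list(er_positive = cohort$er_positive %in% TRUE,
              er_negative = cohort$er_positive %in% FALSE),
    node = list(node_positive = cohort$node_positive %in% TRUE,
                node_negative = cohort$node_positive %in% FALSE),
    grade = list(high_grade = cohort$high_grade %in% TRUE,
                 low_grade = cohort$high_grade %in% FALSE),
    detection = list(interval = cohort$detection_mode %in% "interval",
                     screen_detected =
                       cohort$detection_mode %in% "screen_detected"),
    time_median = {
      med <- stats::median(cohort$time[case])
      list(early = case & cohort$time <= med,
           late = case & cohort$time > med)
    })
  scans <- list()
  skipped <- data.frame(stratum = character(0), n_case_events = integer(0))
  for (nm in names(rules)) {
    keep <- !case | (case & rules[[nm]])
    n_ev <- sum(cohort$event[keep & case])
    if (n_ev < 10) {
      skipped <- rbind(skipped,
                       data.frame(stratum = nm, n_case_events = n_ev))
      next
    }
    sub_ids <- cohort$id[keep]
    sub <- matrix[rownames(matrix) %in% sub_ids, , drop = FALSE]
    scans[[nm]] <- run_scan(sub, cohort[keep, ], adjustment = adjustment,
                            pc_scores = pc_scores, alpha = alpha,
                            ties = ties)
  }
  c(scans, list(skipped = skipped))
}

#' Case-only differential-association test
#'
#' Among cases only, regresses a binary case grouping (for instance
#' interval versus screen-detected cancer) on the protein level with
#' logistic regression, adjusted for case-applicable covariates. The
#' protein coefficient is the log odds ratio of group membership per unit
#' of protein level; a significant coefficient indicates the protein is
#' differentially associated with the two case subtypes.
#'
#' @param protein numeric protein values among cases.
#' @param group logical or two-level factor case grouping.
#' @param covariates optional data.frame of case-level covariates.
#' @return list with `estimate` (log OR), `se`, `p` (Wald), `n`, and
#'   `flag` (`"separation"` when the fit diverges).
#' @export
case_only_test <- function(protein, group, covariates = NULL) {
  if (is.factor(group) || is.character(group))
    group <- group == sort(unique(as.character(group)))[2]
  group <- as.logical(group)
  cc <- !is.na(protein) & !is.na(group)
  if (!is.null(covariates)) cc <- cc & stats::complete.cases(covariates)
  if (min(table(group[cc])) < 10)
    stop_protscan("each case group must have at least 10 members")
  dat <- data.frame(.g = group[cc], .x = protein[cc])
  if (!is.null(covariates)) dat <- cbind(dat, covariates[cc, , drop = FALSE])
  fit <- suppressWarnings(stats::glm(.g ~ ., data = dat,
                                     family = stats::binomial()))
  est <- unname(stats::coef(fit)[".x"])
  se <- sqrt(diag(stats::vcov(fit))[".x"])
  flag <- if (is.finite(est) && abs(est) > 20) "separation" else ""
  list(estimate = est, se = unname(se),
       p = unname(2 * stats::pnorm(-abs(est / se))), n = sum(cc),
       flag = flag)
}
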