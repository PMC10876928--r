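#' Default end-to-end run configuration
#'
#' A nested list mirroring the pipeline stages. `stages` toggles each
#' stage; later stages read the outputs of earlier enabled stages, or the
#' files named under `paths` when the producing stage is disabled.
#' Shipping defaults are the reduced-replicate targeted design so a full
#' run completes in minutes; raise `power$reps` and
#' `power$bisect_reps` for publication-grade precision.
#'
#' @param panel_mode `"targeted"` or `"exploratory"`.
#' @return nested configuration list.
#' @export
default_run_config <- function(panel_mode = "targeted") {
  targeted <- panel_mode == "targeted"
  list(
    panel_mode = panel_mode,
    stages = list(simulate = TRUE, qc = TRUE, scan = TRUE,
                  predict = TRUE, power = TRUE),
    paths = list(cohort = NULL, npx = NULL),
    generator = if (targeted) list() else
      list(n_cases = 303, n_controls = 294, n_proteins = 250,
           centres = "B", panel_mode = "exploratory"),
    qc = list(max_missing = if (targeted) 0.10 else 0.50,
              rule = if (targeted) "per_centre" else "overall",
              drop_qc_warning = TRUE, n_pcs = 10,
              outlier_sd = if (targeted) Inf else 5),
    scan = list(alpha = 0.05, ties = "efron"),
    predict = list(n_folds = 5, n_lambda = 50),
    power = list(target = 0.80, hr_claim = if (targeted) 1.28 else 1.74,
                 reps = 100, bisect_reps = 100, bracket = c(0, 1.5)))
}

#' Read a run configuration from a YAML file
#'
#' Values present in the file override the defaults of
#' [default_run_config()]; unknown keys raise an error naming the field.
#'
#' @param path YAML file.
#' @return nested configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_run_config(user$panel_mode %||% "targeted")
  ## the generator subtree holds cohort_config() overrides: validate its
  ## keys against that function's arguments, then merge it wholesale
  if (!is.null(user$generator)) {
    bad <- setdiff(names(user$generator), names(formals(cohort_config)))
    if (length(bad))
      stop_protscan("unknown configuration field 'generator$%s'", bad[1])
    base$generator <- utils::modifyList(base$generator, user$generator)
    user$generator <- NULL
  }
  merge_config(base, user, "")
}

merge_config <- function(base, user, prefix) {
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(base))
      stop_protscan("unknown configuration field '%s'", full)
    if (is.list(base[[key]]) && is.list(user[[key]]))
      base[[key]] <- merge_config(base[[key]], user[[key]],
                                  paste0(full, "$"))
    else base[[key]] <- user[[key]]
  }
  base
}

#' Run the simulate -> qc -> scan -> predict -> power pipeline
#'
#' Executes the enabled stages in order with one derived seed per
#' stochastic stage, persisting every intermediate product as TSV/CSV in
#' `out_dir`, and returns a consolidated report. A failure in a single
#' protein-level fit is recorded, never fatal to the run.
#'
#' @param config nested list from [default_run_config()] or
#'   [read_run_config()].
#' @param seed master integer seed.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return object of class `run_report`.
#' @export
run_pipeline <- function(config = default_run_config(), seed = 1,
                         out_dir = tempfile("protscan_run_"),
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  st <- config$stages
  report <- list(version = as.character(utils::packageVersion("protscan")),
                 panel_mode = config$panel_mode, seed = seed,
                 config_hash = config_hash(config), stages = list())

  cohort <- NULL; npx <- NULL
  if (isTRUE(st$simulate)) {
    say("stage simulate (seed %d)", seed)
    cfg <- do.call(cohort_config, config$generator)
    sim <- generate_cohort(cfg, seed = derive_seed(seed, "simulate"))
    cohort <- sim$cohort; npx <- sim$npx
    write_cohort(cohort, file.path(out_dir, "cohort.tsv"))
    write_npx_long(npx, file.path(out_dir, "npx_long.csv"))
    write_npx_wide(npx, file.path(out_dir, "npx_wide.tsv"))
    report$stages$simulate <- list(
      n_cases = sum(cohort$is_case), n_controls = sum(!cohort$is_case),
      n_proteins = ncol(npx$values), baseline_hazard = sim$baseline_hazard,
      median_age_cases = stats::median(cohort$age_at_draw[cohort$is_case]),
      median_age_controls =
        stats::median(cohort$age_at_draw[!cohort$is_case]))
  } else if (any(unlist(st[c("qc", "scan", "predict")]))) {
    if (is.null(config$paths$cohort) || is.null(config$paths$npx))
      stop_protscan("stage 'simulate' disabled: paths$cohort and paths$npx are required")
    cohort <- read_cohort(config$paths$cohort)
    npx <- read_npx_long(config$paths$npx)
  }

  norm <- NULL; pcs <- NULL
  if (isTRUE(st$qc)) {
    say("stage qc")
    centres <- cohort$centre[match(rownames(npx$values), cohort$id)]
    filt <- filter_proteins(npx, centres = centres,
                            max_missing = config$qc$max_missing,
                            rule = config$qc$rule,
                            drop_qc_warning = config$qc$drop_qc_warning)
    write_qc_report(filt$report, file.path(out_dir, "qc_report.tsv"))
    norm <- inverse_normal_transform(filt$npx, centres)
    pcs <- compute_pcs(norm, k = config$qc$n_pcs)
    outliers <- if (is.finite(config$qc$outlier_sd))
      flag_pca_outliers(pcs$scores, config$qc$outlier_sd) else character(0)
    if (length(outliers)) {
      keep <- !(rownames(norm) %in% outliers)
      norm <- structure(norm[keep, , drop = FALSE],
                        group = attr(norm, "group")[keep],
                        offset = attr(norm, "offset"),
                        class = class(norm))
      pcs <- compute_pcs(norm, k = config$qc$n_pcs)
    }
    clus <- hierarchical_cluster(npx, labels = centres)
    clus_norm <- hierarchical_cluster(norm, labels =
                                        attr(norm, "group") %||% centres)
    utils::write.table(
      data.frame(sample_id = rownames(pcs$scores), pcs$scores),
      file.path(out_dir, "pc_scores.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    report$stages$qc <- list(
      n_proteins_in = ncol(npx$values),
      n_proteins_dropped = nrow(filt$report),
      dropped = filt$report$protein,
      n_pca_outliers = length(outliers),
      purity_raw = clus$purity, purity_normalized = clus_norm$purity,
      pc1_explained = pcs$explained[1])
  }

  scan <- NULL
  if (isTRUE(st$scan)) {
    say("stage scan")
    if (is.null(norm)) stop_protscan("stage 'scan' needs the qc stage output")
    scan <- run_scan(norm, cohort, pc_scores = pcs$scores,
                     alpha = config$scan$alpha, ties = config$scan$ties)
    write_scan(scan, file.path(out_dir, "associations.tsv"))
    write_manhattan_coords(scan, file.path(out_dir,
                                           "manhattan_coords.tsv"))
    s <- summary(scan)
    eff <- summarize_effect_sizes(scan)
    report$stages$scan <- list(
      m = s$m, n_nominal = s$n_nominal, n_bonferroni = s$n_bonferroni,
      n_fdr = s$n_fdr,
      top_protein = scan$protein[scan$family == "protein"][1],
      top_p = scan$p[scan$family == "protein"][1],
      mean_abs_beta_nominal = eff$mean_abs_beta)
  }

  if (isTRUE(st$predict)) {
    say("stage predict")
    if (is.null(norm)) stop_protscan("stage 'predict' needs the qc stage output")
    base_cols <- c("age_at_draw", "bmi", "percent_density",
                   "postmenopausal", "grs", "family_history")
    co <- cohort[match(rownames(norm), cohort$id), ]
    lpath <- cv_auc_path(unclass(norm), co[, base_cols], co$is_case,
                         n_folds = config$predict$n_folds,
                         seed = derive_seed(seed, "predict"),
                         centre = co$centre)
    write_lasso_path(lpath, file.path(out_dir, "lasso_path.tsv"))
    best <- which.max(lpath$mean_auc)
    report$stages$predict <- list(
      baseline_auc = attr(lpath, "baseline_auc"),
      baseline_se = attr(lpath, "baseline_se"),
      best_auc = lpath$mean_auc[best], best_se = lpath$se_auc[best],
      best_n_proteins = lpath$n_nonzero[best],
      improvement_over_baseline =
        lpath$mean_auc[best] - attr(lpath, "baseline_auc"))
  }

  if (isTRUE(st$power)) {
    say("stage power")
    m <- if (!is.null(scan)) attr(scan, "m") else
      if (config$panel_mode == "targeted") 163 else 2204
    gen <- do.call(cohort_config, config$generator)
    des <- design_spec(gen$n_cases, gen$n_controls, m,
                       centres = gen$centres, horizon = gen$horizon,
                       label = config$panel_mode)
    pseed <- derive_seed(seed, "power")
    claim <- estimate_power(des, log(config$power$hr_claim),
                            reps = config$power$reps, seed = pseed)
    det <- detectable_effect(des, config$power$target,
                             reps = config$power$bisect_reps, seed = pseed,
                             bracket = config$power$bracket)
    curve <- power_curve(des, sort(det$trace$beta),
                         reps = config$power$bisect_reps, seed = pseed)
    write_power_curve(curve, file.path(out_dir, "power_curve.tsv"))
    report$stages$power <- list(
      m = m, hr_claim = config$power$hr_claim,
      power_at_claim = claim$power, power_ci = claim$ci,
      detectable_beta = det$beta, detectable_hr = det$hr,
      target = config$power$target)
  }

  class(report) <- "run_report"
  saveRDS_free_report(report, file.path(out_dir, "report.yaml"))
  report
}

write_manhattan_coords <- function(scan, path) {
  prot <- scan[scan$family == "protein", ]
  coords <- data.frame(protein = prot$protein,
                       index = seq_len(nrow(prot)),
                       neglog10_p = -log10(prot$p),
                       direction = ifelse(prot$beta >= 0, "up", "down"))
  utils::write.table(coords, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

## plain-text (YAML) persistence keeps the deliverable binary-free
saveRDS_free_report <- function(report, path) {
  yaml::write_yaml(unclass(report), path)
  invisible(path)
}

config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  sprintf("%08x", derive_seed(0, txt))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("protscan run report (v%s, %s panel, seed %d, config %s)\n",
              x$version, x$panel_mode, x$seed, x$config_hash))
  s <- x$stages
  if (!is.null(s$simulate))
    cat(sprintf("  simulate: %d cases / %d controls, %d proteins\n",
                s$simulate$n_cases, s$simulate$n_controls,
                s$simulate$n_proteins))
  if (!is.null(s$qc))
    cat(sprintf("  qc      : dropped %d/%d proteins; purity raw %.2f -> normalized %.2f\n",
                s$qc$n_proteins_dropped, s$qc$n_proteins_in,
                s$qc$purity_raw, s$qc$purity_normalized))
  if (!is.null(s$scan))
    cat(sprintf("  scan    : %d/%d nominal, %d Bonferroni, %d FDR hits (top: %s, p = %.3g)\n",
                s$scan$n_nominal, s$scan$m, s$scan$n_bonferroni,
                s$scan$n_fdr, s$scan$top_protein, s$scan$top_p))
  if (!is.null(s$predict))
    cat(sprintf("  predict : baseline AUC %.3f (SE %.3f) vs best path AUC %.3f (%d proteins)\n",
                s$predict$baseline_auc, s$predict$baseline_se,
                s$predict$best_auc, s$predict$best_n_proteins))
  if (!is.null(s$power))
    cat(sprintf("  power   : %.1f%% at HR %.2f; detectable HR at %d%% power: %.3f\n",
                100 * s$power$power_at_claim, s$power$hr_claim,
                round(100 * s$power$target), s$power$detectable_hr))
  invisible(x)
}

#' Validate a cohort table and NPX file pair
#'
#' Checks the column dictionary, id cross-references and unit ranges (ages
#' 18-100 years, BMI 10-70 kg/m^2, times in (0, horizon]) without mutating
#' the inputs.
#'
#' @param cohort_path cohort TSV path.
#' @param npx_path long-format NPX file path.
#' @param horizon follow-up horizon in months.
#' @return data.frame of issues (`rule`, `where`, `message`); zero rows
#'   means the pair is valid.
#' @export
validate_inputs <- function(cohort_path, npx_path, horizon = 36) {
  issues <- data.frame(rule = character(0), where = character(0),
                       message = character(0))
  add <- function(rule, where, message)
    rbind(issues, data.frame(rule = rule, where = where, message = message))
  cohort <- read_cohort(cohort_path)
  need <- c("id", "centre", "age_at_draw", "bmi", "is_case", "time",
            "event")
  for (col in setdiff(need, names(cohort)))
    issues <- add("missing_column", col,
                  sprintf("cohort table lacks required column '%s'", col))
  if (!nrow(issues)) {
    bad_age <- which(cohort$age_at_draw < 18 | cohort$age_at_draw > 100)
    for (i in bad_age)
      issues <- add("age_range", sprintf("row %d", i),
                    sprintf("age %.1f outside [18, 100]", cohort$age_at_draw[i]))
    bad_bmi <- which(cohort$bmi < 10 | cohort$bmi > 70)
    for (i in bad_bmi)
      issues <- add("bmi_range", sprintf("row %d", i),
                    sprintf("BMI %.1f outside [10, 70]", cohort$bmi[i]))
    bad_time <- which(!(cohort$time > 0 & cohort$time <= horizon))
    for (i in bad_time)
      issues <- add("time_range", sprintf("row %d", i),
                    sprintf("time %s outside (0, %d]", cohort$time[i], horizon))
    bad_ev <- which(cohort$event & !cohort$is_case)
    for (i in bad_ev)
      issues <- add("event_without_case", sprintf("row %d", i),
                    "event = TRUE but is_case = FALSE")
    npx <- read_npx_long(npx_path)
    orphan <- setdiff(rownames(npx$values), cohort$id)
    for (id in orphan)
      issues <- add("unknown_sample", id,
                    sprintf("NPX sample id '%s' absent from cohort", id))
  }
  issues
}
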