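test_that("fit_cox matches grid search of the hand-coded partial likelihood", {
  # 3-subject toy: times 1, 2, 3 months, all events; the middle-ranked
  # exposure fails first so the likelihood has an interior maximum
  x <- c(1, -1, 0)
  time <- c(1, 2, 3)
  event <- c(TRUE, TRUE, TRUE)
  rec <- fit_cox(x, NULL, time, event, ties = "breslow", min_events = 1)
  grid <- seq(-5, 5, by = 1e-3)
  ll <- vapply(grid, partial_loglik, numeric(1), x = x / sd(x),
               time = time, event = event)
  expect_lt(abs(rec$beta - grid[which.max(ll)]), 1e-3)

  # exposure perfectly ordered with failure time: monotone partial
  # likelihood, detected and flagged as separation
  sep <- fit_cox(c(-1, 0, 1), NULL, time, event, ties = "breslow",
                 min_events = 1)
  expect_equal(sep$flag, "separation")

  # random small instances without ties agree with the golden-section
  # maximizer of the explicit partial likelihood
  set.seed(12)
  for (r in 1:5) {
    n <- sample(5:8, 1)
    x <- rnorm(n)
    time <- sample(seq_len(50), n)  # distinct times
    event <- c(TRUE, runif(n - 1) < 0.7)
    if (sum(event) < 2) event[2] <- TRUE
    rec <- fit_cox(x, NULL, time, event, ties = "breslow", min_events = 1)
    xs <- (x - mean(x)) / sd(x)
    opt <- optimize(partial_loglik, c(-5, 5), x = xs, time = time,
                    event = event, maximum = TRUE, tol = 1e-8)
    expect_lt(abs(rec$beta - opt$maximum), 1e-3)
  }
})

test_that("fit_cox records are internally consistent and scale-free", {
  sim <- small_sim()
  co <- sim$cohort
  norm <- inverse_normal_transform(sim$npx, co$centre)
  covars <- protscan:::scan_covariates(co)
  rec <- fit_cox(norm[, 1], covars, co$time, co$event)
  expect_equal(rec$hr, exp(rec$beta), tolerance = 1e-12)
  expect_equal(rec$p, 2 * (1 - pnorm(abs(rec$beta / rec$se))),
               tolerance = 1e-12)
  expect_lte(rec$n_events, rec$n_used)
  # invariance under affine rescaling of the raw exposure
  rec2 <- fit_cox(3 * norm[, 1] + 7, covars, co$time, co$event)
  expect_equal(rec2$beta, rec$beta, tolerance = 1e-8)
  expect_equal(rec2$se, rec$se, tolerance = 1e-8)
  expect_error(fit_cox(rep(1, nrow(co)), covars, co$time, co$event),
               "zero variance")
})

test_that("null exposures stay within 3 SE of zero", {
  set.seed(13)
  inside <- 0
  for (r in 1:25) {
    n <- 300
    x <- rnorm(n)
    t_ev <- rexp(n, 0.03)
    event <- t_ev <= 36
    rec <- fit_cox(x, NULL, pmin(t_ev, 36), event)
    if (abs(rec$beta) < 3 * rec$se) inside <- inside + 1
  }
  expect_gte(inside, 23)
})

test_that("multiplicity adjustment matches the hand-computed step-up", {
  expect_equal(adjust_multiplicity(c(0.01, 0.02, 0.04), "bh_fdr"),
               c(0.03, 0.03, 0.04))
  expect_equal(adjust_multiplicity(c(0.01, 0.02, 0.04), "bonferroni"),
               c(0.03, 0.06, 0.12))
  expect_equal(adjust_multiplicity(0.07, "bonferroni"), 0.07)
  expect_equal(adjust_multiplicity(0.07, "bh_fdr"), 0.07)
  expect_equal(adjust_multiplicity(rep(0.02, 5), "bh_fdr"), rep(0.02, 5))
  expect_equal(adjust_multiplicity(c(0.5, 0.9), "bonferroni"), c(1, 1))
  # BH is monotone in the input ordering and idempotent
  set.seed(14)
  p <- runif(40)
  q <- adjust_multiplicity(p, "bh_fdr")
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_equal(adjust_multiplicity(q, "bh_fdr"), q)
  expect_error(adjust_multiplicity(numeric(0)), "empty")
  expect_error(adjust_multiplicity(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("run_scan attaches coherent flags and treats duplicates identically", {
  sim <- small_sim()
  co <- sim$cohort
  norm <- inverse_normal_transform(sim$npx, co$centre)
  dup <- cbind(unclass(norm), DUP = norm[, 2])
  scan <- run_scan(dup, co)
  m <- attr(scan, "m")
  expect_equal(m, ncol(dup))
  a <- scan[scan$protein == colnames(norm)[2], ]
  b <- scan[scan$protein == "DUP", ]
  expect_equal(a$beta, b$beta)
  expect_equal(a$p, b$p)
  expect_true(!is.unsorted(scan$p[scan$family == "protein"]))
  expect_equal(scan$p_bonferroni, pmin(1, m * scan$p))
  expect_true(all(scan$q_fdr >= scan$p))
  expect_equal(scan$nominal, scan$p < 0.05)
  expect_equal(scan$bonferroni_sig, scan$p < 0.05 / m)
  if (min(scan$p) >= 0.05 / m) expect_equal(sum(scan$bonferroni_sig), 0)
})

test_that("PC exposures form their own multiplicity family", {
  sim <- small_sim()
  co <- sim$cohort
  norm <- inverse_normal_transform(sim$npx, co$centre)
  pcs <- compute_pcs(norm, k = 3)
  scan <- run_scan(norm, co, pc_scores = pcs$scores)
  pc_rows <- scan[scan$family == "pc", ]
  expect_equal(nrow(pc_rows), 3)
  expect_equal(pc_rows$p_bonferroni, pmin(1, 3 * pc_rows$p))
})

test_that("scan p-values are uniform under the global null", {
  # pooled p-values from replicate null scans pass a KS uniformity test;
  # proteins are generated without shared factors here so the pooled
  # p-values are independent and the KS reference distribution applies
  pvals <- c()
  for (r in 1:7) {
    sim <- generate_cohort(cohort_config(loading_sd = 0), seed = 7000 + r)
    norm <- inverse_normal_transform(sim$npx, sim$cohort$centre)
    scan <- run_scan(norm, sim$cohort)
    pvals <- c(pvals, scan$p[scan$family == "protein"])
  }
  expect_gte(length(pvals), 1000)
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
  # nominal fraction close to alpha
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.015)
})

test_that("the scan's fast fitting path equals the formula interface", {
  sim <- small_sim()
  co <- sim$cohort
  norm <- inverse_normal_transform(sim$npx, co$centre)
  scan <- run_scan(norm, co)
  covars <- protscan:::scan_covariates(co)
  pid <- scan$protein[1]
  ref <- fit_cox(norm[, pid], covars, co$time, co$event, id = pid)
  expect_equal(scan$beta[1], ref$beta, tolerance = 1e-10)
  expect_equal(scan$se[1], ref$se, tolerance = 1e-10)
  expect_equal(scan$p[1], ref$p, tolerance = 1e-10)
})

test_that("stratified scan with a rule keeping all cases equals the plain scan", {
  sim <- generate_cohort(
    cohort_config(n_cases = 80, n_controls = 80, n_proteins = 8,
                  match_tolerance = 2, p_interval = 1),
    seed = 55)
  co <- sim$cohort
  norm <- inverse_normal_transform(sim$npx, co$centre)
  strat <- stratified_scan(norm, co, stratum = "detection")
  expect_named(strat, c("interval", "skipped"))
  expect_equal(strat$skipped$stratum, "screen_detected")
  plain <- run_scan(norm, co)
  expect_equal(as.data.frame(strat$interval), as.data.frame(plain))
})

test_that("case-only test recovers the 2x2 log odds ratio", {
  # dichotomized protein, counts 30/10 vs 10/30: log OR = log(9)
  protein <- rep(c(1, 0, 1, 0), c(30, 10, 10, 30))
  group <- rep(c(TRUE, FALSE), each = 40)
  res <- case_only_test(protein, group)
  expect_lt(abs(res$estimate - log(9)), 1e-6)
  expect_lt(res$p, 0.05)
  expect_error(case_only_test(rnorm(20), rep(c(TRUE, FALSE), c(15, 5))),
               "at least 10")
})

test_that("case-only test detects a group-specific shift by simulation", {
  set.seed(15)
  rejections <- 0
  for (r in 1:60) {
    protein <- c(rnorm(150, 0.5), rnorm(150, 0))
    group <- rep(c(TRUE, FALSE), each = 150)
    if (case_only_test(protein, group)$p < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / 60, 0.5)
})

test_that("stratified scans recover a detection-mode-specific association", {
  # among cases, make interval detection more likely at high protein level:
  # the interval-stratum estimate should exceed the screen-detected one,
  # while under an effect shared by both strata the difference stays at 0
  diff_specific <- diff_shared <- numeric(10)
  for (r in 1:10) {
    cfg <- cohort_config(n_cases = 150, n_controls = 150, n_proteins = 1,
                         missing_rate = 0, match_tolerance = 2,
                         p_interval = 0.5,
                         effects = effect_spec(proteins = c(P0001 = 0.3)))
    sim <- generate_cohort(cfg, seed = 8000 + r)
    co <- sim$cohort
    norm <- inverse_normal_transform(sim$npx, co$centre)
    strat <- stratified_scan(norm, co, stratum = "detection")
    diff_shared[r] <- strat$interval$beta[1] - strat$screen_detected$beta[1]
    # reassign detection mode with probability rising in the protein level
    set.seed(900 + r)
    cases <- co$is_case
    z <- norm[match(co$id[cases], rownames(norm)), 1]
    co$detection_mode[cases] <- ifelse(runif(sum(cases)) < plogis(1.5 * z),
                                       "interval", "screen_detected")
    strat2 <- stratified_scan(norm, co, stratum = "detection")
    diff_specific[r] <- strat2$interval$beta[1] -
      strat2$screen_detected$beta[1]
  }
  expect_lt(abs(mean(diff_shared)), 0.12)
  expect_gt(mean(diff_specific), 0.25)
})
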