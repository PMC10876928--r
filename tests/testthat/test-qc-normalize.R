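test_that("protein filtering applies the per-centre and overall rules", {
  # protein P01 missing in 3/20 centre-A samples (15%), complete in B
  v <- matrix(rnorm(40 * 3), 40, 3)
  v[1:3, 1] <- NA
  npx <- toy_npx(v)
  centres <- rep(c("A", "B"), each = 20)

  per_centre <- filter_proteins(npx, centres, max_missing = 0.10,
                                rule = "per_centre")
  expect_equal(per_centre$report$protein, "P01")
  expect_equal(per_centre$report$reason, "missing_gt_threshold")
  expect_false("P01" %in% colnames(per_centre$npx$values))

  # same matrix under the single-group exploratory rule: 3/40 = 7.5% <= 50%
  overall <- filter_proteins(npx, max_missing = 0.50, rule = "overall")
  expect_equal(nrow(overall$report), 0)
  expect_equal(ncol(overall$npx$values), 3)

  # nothing to filter
  clean <- filter_proteins(toy_npx(matrix(rnorm(40), 20, 2)),
                           rep("A", 20), max_missing = 0.10)
  expect_equal(nrow(clean$report), 0)

  # QC warnings carry their own reason code; max_missing = 1 retains the rest
  warned <- toy_npx(matrix(rnorm(60), 20, 3),
                    qc_warning = c(TRUE, FALSE, FALSE))
  res <- filter_proteins(warned, rep("A", 20), max_missing = 1)
  expect_equal(res$report$reason, "qc_warning")
  expect_equal(ncol(res$npx$values), 2)
  res2 <- filter_proteins(warned, rep("A", 20), max_missing = 1,
                          drop_qc_warning = FALSE)
  expect_equal(ncol(res2$npx$values), 3)
})

test_that("below-LOD fractions count non-missing values under the limit", {
  v <- matrix(10, 2, 10)
  v[2, 1:3] <- 1  # 3 of 10 below
  npx <- toy_npx(v, lod = rep(5, 10))
  expect_equal(unname(pct_below_lod(npx)), c(0, 0.3))
  # all above LOD
  expect_equal(unname(pct_below_lod(toy_npx(matrix(9, 3, 4),
                                            lod = rep(1, 4)))),
               rep(0, 3))
  # missing values are excluded from numerator and denominator
  v[2, 4:8] <- NA
  npx2 <- toy_npx(v, lod = rep(5, 10))
  expect_equal(unname(pct_below_lod(npx2))[2], 3 / 5)
  v[2, ] <- NA
  expect_error(pct_below_lod(toy_npx(v, lod = rep(5, 10))),
               "no non-missing")
})

test_that("INT maps ranks to the exact normal quantiles", {
  m <- matrix(c(5.1, 2.0, 3.3), 3, 1,
              dimnames = list(paste0("s", 1:3), "P1"))
  out <- inverse_normal_transform(m, rep("A", 3))
  expect_equal(as.numeric(out), qnorm(c(5, 1, 3) / 6), tolerance = 1e-12)
  expect_equal(as.numeric(out)[3], 0)  # median of an odd group is exactly 0

  # multiset of outputs is {qnorm((r - 0.5)/n)} and the mean is exactly 0
  set.seed(3)
  x <- matrix(rnorm(25), 25, 1, dimnames = list(NULL, "P"))
  y <- inverse_normal_transform(x, rep("A", 25))
  expect_equal(sort(as.numeric(y)), qnorm(((1:25) - 0.5) / 25),
               tolerance = 1e-12)
  expect_lt(abs(mean(y)), 1e-6)

  # Blom offset variant
  yb <- inverse_normal_transform(x, rep("A", 25), offset = 3 / 8)
  expect_equal(sort(as.numeric(yb)),
               qnorm(((1:25) - 3 / 8) / (25 + 0.25)), tolerance = 1e-12)
})

test_that("INT is invariant to monotone transforms and removes group shifts", {
  set.seed(4)
  v <- matrix(rexp(60), 30, 2, dimnames = list(NULL, c("Pa", "Pb")))
  v[c(3, 17), 1] <- NA
  g <- rep(c("A", "B"), 15)
  v[g == "B", ] <- v[g == "B", ] + 50  # gross centre shift
  a <- inverse_normal_transform(v, g)
  b <- inverse_normal_transform(exp(v / 10) * 3 - 1, g)  # strictly monotone
  expect_equal(unclass(a), unclass(b), tolerance = 1e-12)
  expect_true(all(is.na(a[c(3, 17), 1])))
  for (gg in c("A", "B"))
    expect_lt(max(abs(colMeans(a[g == gg, ], na.rm = TRUE))), 1e-6)

  # constant protein: all-tied ranks map to zero and are flagged
  v2 <- cbind(v, Pc = rep(7, 30))
  out <- inverse_normal_transform(v2, g)
  expect_true(all(out[, "Pc"] == 0))
  expect_true(all(vapply(attr(out, "constant_proteins"),
                         function(z) "Pc" %in% z, logical(1))))
})

test_that("principal components are ordered, signed and reconstruct the data", {
  # rank-1 input: PC1 carries all the variance
  u <- outer(rnorm(20), c(1, 2, -1))
  pc1 <- compute_pcs(u +
    matrix(rnorm(60, 0, 1e-8), 20, 3), k = 3)
  expect_gt(pc1$explained[1], 0.999999)

  set.seed(5)
  m <- matrix(rnorm(50 * 20), 50, 20)
  pc <- compute_pcs(m, k = 20)
  recon <- pc$scores %*% t(pc$loadings)
  centred <- scale(m, scale = FALSE)
  expect_lt(max(abs(recon - centred)), 1e-8)
  expect_true(all(diff(pc$explained) <= 1e-12))
  # sign convention: the largest-magnitude loading of each PC is positive
  for (j in seq_len(20))
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  expect_error(compute_pcs(m, k = 0), "positive")
})

test_that("PCA outlier flagging is a per-component threshold rule", {
  set.seed(6)
  s <- matrix(rnorm(200), 100, 2, dimnames = list(sprintf("s%03d", 1:100),
                                                  c("PC1", "PC2")))
  expect_length(flag_pca_outliers(s, k_sd = 5), 0)
  expect_length(flag_pca_outliers(s, k_sd = Inf), 0)
  s[7, 1] <- 10 * sd(s[, 1])
  expect_equal(flag_pca_outliers(s, k_sd = 5), "s007")
  expect_error(flag_pca_outliers(s[1:5, ], 5), "at least 10")
})

test_that("Euclidean distances and blob clustering match brute force", {
  set.seed(7)
  m <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(paste0("s", 1:8), NULL))
  d <- as.matrix(dist(m))
  for (i in 1:8) for (j in 1:8) {
    acc <- 0
    for (p in 1:5) acc <- acc + (m[i, p] - m[j, p])^2
    expect_lt(abs(d[i, j] - sqrt(acc)), 1e-10)
  }
  # two well-separated blobs are recovered perfectly
  blob <- rbind(matrix(rnorm(100, 0), 20, 5),
                matrix(rnorm(100, 10), 20, 5))
  rownames(blob) <- sprintf("b%02d", 1:40)
  hc <- hierarchical_cluster(blob, labels = rep(c("x", "y"), each = 20))
  expect_equal(hc$purity, 1)
})

test_that("clustering separates centres on raw NPX but not after INT", {
  sim <- generate_cohort(cohort_config(n_cases = 150, n_controls = 150,
                                       match_tolerance = 1.5), seed = 77)
  centres <- sim$cohort$centre
  raw <- hierarchical_cluster(sim$npx, labels = centres)
  expect_gt(raw$purity, 0.9)
  norm <- inverse_normal_transform(sim$npx, centres)
  post <- hierarchical_cluster(norm, labels = centres)
  expect_lt(post$purity, 0.75)  # near chance once the shift is removed
})
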