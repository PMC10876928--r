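# Shared fixtures, generated in code at test time.

# A small two-centre simulated cohort reused across files (generated once).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(
        cohort_config(n_cases = 60, n_controls = 60, n_proteins = 12,
                      match_tolerance = 2),
        seed = 101)
    cache
  }
})

# A bare NPX matrix with controllable missingness for QC tests.
toy_npx <- function(values, lod = NULL, panel = "targeted_CAM",
                    qc_warning = NULL) {
  if (is.null(dimnames(values)))
    dimnames(values) <- list(sprintf("s%02d", seq_len(nrow(values))),
                             sprintf("P%02d", seq_len(ncol(values))))
  if (is.null(lod)) lod <- rep(-Inf, ncol(values))
  npx_matrix(values, lod, panel, qc_warning)
}

# Hand-coded Cox partial log-likelihood (Breslow form, no ties expected)
# for the oracle comparisons; independent of the survival package.
partial_loglik <- function(beta, x, time, event) {
  ord <- order(time)
  x <- x[ord]; time <- time[ord]; event <- event[ord]
  ll <- 0
  for (i in seq_along(time)) {
    if (!event[i]) next
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Brute-force AUC by explicit pair enumeration.
auc_bruteforce <- function(scores, labels) {
  labels <- as.logical(labels)
  ca <- scores[labels]; co <- scores[!labels]
  tot <- 0
  for (a in ca) for (b in co)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ca) * length(co))
}
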