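#' Filter proteins by missingness and QC warnings
#'
#' Implements the two panel-specific exclusion rules: under the per-centre
#' rule (targeted panels) a protein is dropped when its missing fraction
#' exceeds `max_missing` in any single recruitment centre; under the
#' single-group rule (exploratory panel) the fraction is computed over all
#' samples. Proteins carrying a vendor-style QC warning can be dropped as
#' well.
#'
#' @param npx an [npx_matrix()].
#' @param centres per-sample centre labels (required for `rule =
#'   "per_centre"`).
#' @param max_missing maximal tolerated missing fraction, in (0, 1]
#'   (0.10 for the targeted rule, 0.50 for the exploratory rule).
#' @param rule `"per_centre"` or `"overall"`.
#' @param drop_qc_warning drop proteins flagged by the vendor QC.
#' @return list with elements `npx` (filtered matrix) and `report` (a
#'   `qc_report`: data.frame of dropped proteins with reason codes
#'   `missing_gt_threshold` / `qc_warning`, plus per-protein missing
#'   fractions as attribute `missing_fractions`).
#' @export
filter_proteins <- function(npx, centres = NULL, max_missing = 0.10,
                            rule = c("per_centre", "overall"),
                            drop_qc_warning = TRUE) {
  rule <- match.arg(rule)
  v <- npx$values
  if (ncol(v) == 0 || nrow(v) == 0) stop_protscan("empty NPX matrix")
  if (max_missing <= 0 || max_missing > 1)
    stop_protscan("max_missing must be in (0, 1]")
  if (rule == "per_centre") {
    if (is.null(centres)) stop_protscan("per-centre rule requires centre labels")
    if (length(centres) != nrow(v))
      stop_protscan("centre labels must cover all %d samples", nrow(v))
    frac <- t(sapply(split(seq_len(nrow(v)), centres), function(i)
      colMeans(is.na(v[i, , drop = FALSE]))))
    if (ncol(v) == 1L) frac <- matrix(frac, ncol = 1)  # sapply simplification
    worst <- apply(frac, 2, max)
  } else {
    frac <- matrix(colMeans(is.na(v)), nrow = 1,
                   dimnames = list("all", colnames(v)))
    worst <- frac[1, ]
  }
  drop_missing <- worst > max_missing
  drop_qc <- drop_qc_warning & npx$qc_warning & !drop_missing
  report <- data.frame(
    protein = colnames(v)[drop_missing | drop_qc],
    reason = ifelse(drop_missing[drop_missing | drop_qc],
                    "missing_gt_threshold", "qc_warning"),
    stringsAsFactors = FALSE)
  keep <- !(drop_missing | (drop_qc_warning & npx$qc_warning))
  if (!any(keep)) stop_protscan("all proteins dropped by QC")
  out <- npx[, which(keep)]
  attr(report, "missing_fractions") <- frac
  class(report) <- c("qc_report", "data.frame")
  list(npx = out, report = report)
}

#' Per-sample fraction of proteins below the detection limit
#'
#' For each sample, the number of non-missing measurements strictly below
#' the protein's LOD divided by the number of non-missing measurements.
#'
#' @param npx an [npx_matrix()].
#' @return named numeric vector, one fraction in [0, 1] per sample.
#' @export
pct_below_lod <- function(npx) {
  v <- npx$values
  if (any(!is.finite(npx$lod))) stop_protscan("LOD missing for some proteins")
  n_obs <- rowSums(!is.na(v))
  if (any(n_obs == 0))
    stop_protscan("sample(s) with no non-missing proteins: %s",
                  paste(rownames(v)[n_obs == 0], collapse = ", "))
  below <- sweep(v, 2, npx$lod, "<")
  rowSums(below, na.rm = TRUE) / n_obs
}

#' Rank-based inverse normal transformation per group
#'
#' Within each group (recruitment centre), every protein's non-missing
#' values are replaced by \eqn{\Phi^{-1}((r - c) / (n - 2c + 1))} where r is
#' the value's rank (average rank for ties), n the group's non-missing count
#' and c the offset constant. The symmetric offset c = 0.5 (default) gives
#' exactly mean-zero output; c = 3/8 is the Blom variant. The output depends
#' on the data only through ranks, so it is identical for any strictly
#' monotone marginal transform of the input and removes systematic
#' between-group level differences.
#'
#' @param npx an [npx_matrix()] (or a bare numeric matrix).
#' @param group per-sample group labels (e.g. centre).
#' @param offset rank offset constant c (0.5 or 3/8).
#' @return object of class `normalized_matrix`: the transformed numeric
#'   matrix with attributes `group` (labels), `offset`, and
#'   `constant_proteins` (per-group list of proteins that were all-tied and
#'   mapped to zero).
#' @export
#' @examples
#' m <- matrix(c(5.1, 2.0, 3.3), 3, 1,
#'             dimnames = list(paste0("s", 1:3), "P1"))
#' inverse_normal_transform(m, group = rep("A", 3))
inverse_normal_transform <- function(npx, group, offset = 0.5) {
  v <- if (inherits(npx, "npx_matrix")) npx$values else npx
  if (length(group) != nrow(v))
    stop_protscan("group labels must cover all %d samples", nrow(v))
  out <- v
  flagged <- list()
  for (g in unique(group)) {
    rows <- which(group == g)
    const <- character(0)
    for (j in seq_len(ncol(v))) {
      x <- v[rows, j]
      obs <- which(!is.na(x))
      if (length(obs) < 2)
        stop_protscan("protein %s has < 2 non-missing values in group %s",
                      colnames(v)[j], g)
      r <- rank(x[obs], ties.method = "average")
      n <- length(obs)
      q <- (r - offset) / (n - 2 * offset + 1)
      y <- stats::qnorm(q)
      if (all(r == r[1])) {  # constant protein: all ranks tied
        y <- rep(0, n)
        const <- c(const, colnames(v)[j])
      }
      out[rows[obs], j] <- y
    }
    if (length(const)) flagged[[g]] <- const
  }
  structure(out, group = group, offset = offset,
            constant_proteins = flagged,
            class = c("normalized_matrix", class(out)))
}

#' Principal components of a normalized protein matrix
#'
#' Columns are mean-centred; missing entries are mean-imputed per protein
#' within group beforehand (per-protein overall mean if no grouping is
#' available). Components are ordered by decreasing explained variance and
#' each component's sign is fixed so its largest-magnitude loading is
#' positive.
#'
#' @param matrix a `normalized_matrix` (or numeric matrix; `NA` allowed).
#' @param k number of components (default 10).
#' @param group optional per-sample labels for within-group mean imputation;
#'   taken from the `normalized_matrix` attribute when present.
#' @return list with `scores` (samples x k), `loadings` (proteins x k) and
#'   `explained` (fraction of variance per component).
#' @export
compute_pcs <- function(matrix, k = 10, group = NULL) {
  if (k <= 0) stop_protscan("k must be positive")
  v <- unclass(matrix)
  attributes(v)[setdiff(names(attributes(v)), c("dim", "dimnames"))] <- NULL
  group <- group %||% attr(matrix, "group") %||% rep("all", nrow(v))
  if (anyNA(v)) {
    for (g in unique(group)) {
      rows <- which(group == g)
      sub <- v[rows, , drop = FALSE]
      mns <- colMeans(sub, na.rm = TRUE)
      idx <- which(is.na(sub), arr.ind = TRUE)
      if (nrow(idx)) sub[idx] <- mns[idx[, 2]]
      v[rows, ] <- sub
    }
  }
  k <- min(k, nrow(v), ncol(v))
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- apply(loadings, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2, flip, "*")
  loadings <- sweep(loadings, 2, flip, "*")
  list(scores = scores, loadings = loadings,
       explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Flag samples as PCA outliers
#'
#' A sample is flagged when its absolute score on PC1 or PC2 exceeds
#' `k_sd` standard deviations of that component's scores.
#'
#' @param scores samples x components score matrix from [compute_pcs()].
#' @param k_sd threshold in SD units (default 5).
#' @return character vector of flagged sample ids (row names), or integer
#'   indices if the matrix has no row names.
#' @export
flag_pca_outliers <- function(scores, k_sd = 5) {
  if (is.list(scores)) scores <- scores$scores
  if (nrow(scores) < 10)
    stop_protscan("need at least 10 samples to flag outliers")
  use <- scores[, seq_len(min(2, ncol(scores))), drop = FALSE]
  sds <- apply(use, 2, stats::sd)
  bad <- rowSums(sweep(abs(use), 2, k_sd * sds, ">")) > 0
  if (!is.null(rownames(scores))) rownames(scores)[bad] else which(bad)
}

#' Agglomerative clustering of samples by Euclidean distance
#'
#' Clusters samples of a raw NPX matrix by pairwise Euclidean distance, as
#' a diagnostic for systematic sample structure such as recruitment-centre
#' batch effects. Missing entries are imputed with the protein's overall
#' mean first (a neutral fill that cannot create group structure by
#' itself). A two-cluster cut is cross-tabulated against reference labels
#' via a purity score when labels are supplied.
#'
#' @param npx an [npx_matrix()] or numeric matrix.
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default Ward, which is the most reliable at recovering mean-shift
#'   structure in these panels).
#' @param k number of clusters for the cut (default 2).
#' @param labels optional per-sample reference labels (e.g. centre) for the
#'   purity diagnostic.
#' @return list with `hclust` (merge tree), `order` (leaf order), `cut`
#'   (cluster labels) and, when `labels` is given, `purity`.
#' @export
hierarchical_cluster <- function(npx, linkage = "ward.D2", k = 2,
                                 labels = NULL) {
  v <- if (inherits(npx, "npx_matrix")) npx$values else npx
  if (nrow(v) < 2) stop_protscan("need at least 2 samples to cluster")
  if (anyNA(v)) {
    mns <- colMeans(v, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- mns[idx[, 2]]
  }
  d <- stats::dist(v, method = "euclidean")
  hc <- stats::hclust(d, method = linkage)
  cut <- stats::cutree(hc, k = k)
  out <- list(hclust = hc, order = hc$order, cut = cut)
  if (!is.null(labels)) out$purity <- cluster_purity(cut, labels)
  out
}

#' Purity of a clustering against reference labels
#'
#' The fraction of samples correctly assigned under the best matching of
#' cluster ids to label values (maximum over label pairings of the matched
#' fraction; for two clusters and two labels this is the larger of the two
#' diagonal sums of the 2 x 2 cross-tabulation).
#'
#' @param cut cluster assignments.
#' @param labels reference labels.
#' @return purity in [0, 1].
#' @export
cluster_purity <- function(cut, labels) {
  tab <- table(cut, labels)
  if (nrow(tab) == 2 && ncol(tab) == 2)
    return(max(tab[1, 1] + tab[2, 2], tab[1, 2] + tab[2, 1]) / sum(tab))
  sum(apply(tab, 1, max)) / sum(tab)
}

#' Write a QC report as TSV
#' @param report a `qc_report` from [filter_proteins()]
#' @param path output file
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
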