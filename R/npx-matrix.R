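#' Construct an NPX matrix container
#'
#' Holds a samples x proteins matrix of NPX values (log2-like arbitrary
#' units) with per-protein detection limits, panel labels and QC flags.
#' Missing measurements are `NA` in `values`; the missing mask is always
#' `is.na(values)` so mask and values cannot disagree.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   proteins in columns (colnames = protein ids); `NA` marks missing.
#' @param lod numeric vector of per-protein detection limits, one per column.
#' @param panel character/factor vector of per-protein panel labels, one of
#'   `"targeted_CAM"`, `"targeted_IMONC"`, `"exploratory"`.
#' @param qc_warning logical vector of per-protein vendor-style QC warnings.
#' @return object of class `npx_matrix`.
#' @export
npx_matrix <- function(values, lod, panel, qc_warning = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_protscan("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_protscan("`values` must carry sample ids (rownames) and protein ids (colnames)")
  p <- ncol(values)
  if (length(lod) != p) stop_protscan("`lod` must have one entry per protein")
  panel <- as.character(panel)
  if (length(panel) == 1L) panel <- rep(panel, p)
  if (length(panel) != p) stop_protscan("`panel` must have one label per protein")
  ok <- panel %in% c("targeted_CAM", "targeted_IMONC", "exploratory")
  if (!all(ok)) stop_protscan("unknown panel label: %s", panel[!ok][1])
  if (is.null(qc_warning)) qc_warning <- rep(FALSE, p)
  if (length(qc_warning) != p)
    stop_protscan("`qc_warning` must have one flag per protein")
  lod <- as.numeric(lod)
  qc_warning <- as.logical(qc_warning)
  names(lod) <- names(panel) <- names(qc_warning) <- colnames(values)
  structure(list(values = values, lod = lod, panel = panel,
                 qc_warning = qc_warning),
            class = "npx_matrix")
}

#' @export
print.npx_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("NPX matrix: %d samples x %d proteins (%s)\n",
              nrow(v), ncol(v),
              paste(unique(x$panel), collapse = ", ")))
  cat(sprintf("  missing: %.2f%%   below LOD: %.2f%% of non-missing\n",
              100 * mean(is.na(v)),
              100 * mean(sweep(v, 2, x$lod, "<"), na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.npx_matrix <- function(x) dim(x$values)

#' Subset an NPX matrix by samples and/or proteins
#' @param x an `npx_matrix`
#' @param i sample index (ids, positions or logical)
#' @param j protein index
#' @param ... unused
#' @export
`[.npx_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  npx_matrix(x$values[i, j, drop = FALSE], x$lod[j], x$panel[j],
             x$qc_warning[j])
}

# ---- I/O -------------------------------------------------------------------

#' Write an NPX matrix in Olink-style long format
#'
#' One CSV row per sample x protein measurement with columns SampleID,
#' Panel, Assay, NPX, LOD, QC_Warning. Missing measurements are written with
#' an empty NPX field so the full design is preserved.
#'
#' @param npx an `npx_matrix`
#' @param path output file
#' @export
write_npx_long <- function(npx, path) {
  v <- npx$values
  long <- data.frame(
    SampleID = rep(rownames(v), times = ncol(v)),
    Panel = rep(npx$panel, each = nrow(v)),
    Assay = rep(colnames(v), each = nrow(v)),
    NPX = as.vector(v),
    LOD = rep(npx$lod, each = nrow(v)),
    QC_Warning = rep(ifelse(npx$qc_warning, "WARN", "PASS"), each = nrow(v)),
    stringsAsFactors = FALSE)
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read an Olink-style long-format NPX file
#'
#' Accepts comma, tab or semicolon delimited files (sniffed from the header
#' line); requires columns SampleID, Panel, Assay, NPX, LOD and optionally
#' QC_Warning.
#'
#' @param path input file
#' @return an `npx_matrix`
#' @export
read_npx_long <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- sniff_delimiter(header, path)
  long <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("SampleID", "Panel", "Assay", "NPX", "LOD")
  miss <- setdiff(need, names(long))
  if (length(miss))
    stop_protscan("NPX file %s lacks required column(s): %s", path,
                  paste(miss, collapse = ", "))
  samples <- unique(long$SampleID)
  proteins <- unique(long$Assay)
  v <- matrix(NA_real_, length(samples), length(proteins),
              dimnames = list(samples, proteins))
  v[cbind(match(long$SampleID, samples), match(long$Assay, proteins))] <-
    long$NPX
  first <- long[!duplicated(long$Assay), ]
  first <- first[match(proteins, first$Assay), ]
  qc <- if ("QC_Warning" %in% names(long)) first$QC_Warning %in%
    c("WARN", "TRUE", "1") else rep(FALSE, length(proteins))
  npx_matrix(v, first$LOD, first$Panel, qc)
}

#' Write an NPX matrix as a wide TSV (samples x proteins)
#' @param npx an `npx_matrix`
#' @param path output file
#' @export
write_npx_wide <- function(npx, path) {
  df <- data.frame(sample_id = rownames(npx$values), npx$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort table as TSV
#'
#' One row per participant. Column dictionary: `id`; `centre` (A/B);
#' `age_at_draw` (years); `bmi` (kg/m^2); logical covariates
#' `postmenopausal`, `ever_smoked`, `lipid_med`, `heart_med`,
#' `renal_failure`, `family_history`; `percent_density` (fraction);
#' `grs` (unitless); `plasma_age` (years); `pct_below_lod` (fraction);
#' `is_case`; `time` (months since blood draw); `event`; case-only fields
#' `detection_mode` (interval/screen_detected), `er_positive`,
#' `node_positive`, `high_grade`.
#'
#' @param cohort a cohort `data.frame`
#' @param path output file
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a cohort TSV written by [write_cohort()]
#' @param path input file
#' @return data.frame
#' @export
read_cohort <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA")
}

sniff_delimiter <- function(header, path) {
  counts <- c("\t" = lengths(regmatches(header, gregexpr("\t", header))),
              "," = lengths(regmatches(header, gregexpr(",", header))),
              ";" = lengths(regmatches(header, gregexpr(";", header))))
  if (all(counts == 0))
    stop_protscan(paste0("cannot detect delimiter of %s: expected tab, ",
                         "comma or semicolon in the header"), path)
  names(which.max(counts))
}
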