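#' Keep features expressed in a minimum fraction of samples
#'
#' RNA-seq abundance matrices carry many features that are zero in most
#' samples; rank correlations on such features are dominated by ties.
#' This filter retains exactly the features whose fraction of non-zero
#' values across all samples is at least `min_frac` (default 0.8).
#'
#' @param m an [expr_matrix] on any scale.
#' @param min_frac minimum non-zero fraction in (0, 1].
#' @return the filtered [expr_matrix]; the sample set is unchanged.
#' @export
filter_nonzero_features <- function(m, min_frac = 0.8) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!(min_frac > 0 && min_frac <= 1)) stop("`min_frac` must be in (0, 1]")
  if (nrow(m$values) == 0 || ncol(m$values) == 0) {
    stop("cannot filter an empty expression matrix")
  }
  frac <- rowMeans(m$values != 0)
  em_replace(m, m$values[frac >= min_frac, , drop = FALSE])
}

#' Upper-quartile normalization
#'
#' Divides every sample by the 75th percentile of its non-zero values,
#' then multiplies all samples by the geometric mean of those per-sample
#' quartiles so that output stays on the original magnitude scale. After
#' the operation every sample has the same non-zero upper quartile.
#'
#' @param m an [expr_matrix] on the FPKM scale.
#' @return the normalized [expr_matrix] (still FPKM scale).
#' @export
upper_quartile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "fpkm") stop("upper-quartile normalization expects FPKM scale")
  uq <- apply(m$values, 2, function(col) {
    nz <- col[col != 0]
    if (length(nz) == 0) return(NA_real_)
    stats::quantile(nz, 0.75, names = FALSE)
  })
  if (anyNA(uq)) {
    stop("sample(s) with no non-zero values: ",
         paste(samples(m)[is.na(uq)], collapse = ", "))
  }
  ref <- exp(mean(log(uq)))
  em_replace(m, sweep(m$values, 2, uq, "/") * ref)
}

#' Shifted log2 transformation
#'
#' Finds the minimum non-zero element of the whole matrix, adds it
#' element-wise, and takes log2. Zeros therefore map to `log2(min)` and
#' the transform is strictly monotone, so within-sample value orderings
#' are preserved.
#'
#' @param m an [expr_matrix] on the FPKM scale with at least one non-zero
#'   element.
#' @return an [expr_matrix] on the log2 scale.
#' @export
log2_shift_transform <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "fpkm") stop("log2 transform expects FPKM scale")
  nz <- m$values[m$values != 0]
  if (length(nz) == 0) stop("all-zero matrix cannot be log-transformed")
  em_replace(m, log2(m$values + min(nz)), scale = "log2")
}

#' Remove outlier samples by mean expression
#'
#' Computes each sample's mean log2 expression and removes samples whose
#' mean lies strictly beyond `k_sd` standard deviations from the
#' across-sample mean of those means. Samples exactly at the boundary are
#' kept.
#'
#' @param m an [expr_matrix] on the log2 scale with at least 3 samples.
#' @param k_sd positive multiplier of the standard deviation (default 2).
#' @return the [expr_matrix] without outlying samples.
#' @export
remove_outlier_samples <- function(m, k_sd = 2) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log2") stop("outlier removal expects log2 scale")
  if (k_sd <= 0) stop("`k_sd` must be positive")
  if (ncol(m$values) < 3) stop("need at least 3 samples for outlier detection")
  mu <- colMeans(m$values)
  s <- stats::sd(mu)
  keep <- if (s == 0) rep(TRUE, length(mu)) else abs(mu - mean(mu)) <= k_sd * s
  em_replace(m, m$values[, keep, drop = FALSE])
}

#' Split a gene matrix into mRNA and lncRNA matrices by biotype
#'
#' Protein-coding features go to the mRNA matrix; lincRNA and antisense
#' features go to the lncRNA matrix. Features with any other biotype, or
#' absent from the table, are dropped (their count is reported in a
#' message rather than guessed at).
#'
#' @param m an [expr_matrix] holding a mixed gene matrix.
#' @param biotype_table data frame with columns `feature` and `biotype`.
#' @return list with elements `mRNA` and `lncRNA`, both [expr_matrix]
#'   objects (possibly with zero rows).
#' @export
partition_by_biotype <- function(m, biotype_table) {
  stopifnot(inherits(m, "expr_matrix"),
            all(c("feature", "biotype") %in% names(biotype_table)))
  bt <- biotype_table$biotype[match(features(m), biotype_table$feature)]
  is_mrna <- !is.na(bt) & bt == "protein_coding"
  is_lnc <- !is.na(bt) & bt %in% c("lincRNA", "antisense")
  dropped <- sum(!is_mrna & !is_lnc)
  if (dropped > 0) {
    message(sprintf("partition_by_biotype: dropped %d feature(s) with other/unannotated biotype", dropped))
  }
  list(
    mRNA = expr_matrix(m$values[is_mrna, , drop = FALSE], "mRNA", m$scale),
    lncRNA = expr_matrix(m$values[is_lnc, , drop = FALSE], "lncRNA", m$scale)
  )
}

#' Split a matrix by subtype and drop lowly expressed features
#'
#' Partitions the samples by their subtype label and, within each
#' subtype, removes features whose median FPKM is at or below
#' `threshold` (the `<=` rule, so a median of exactly 0.7 is removed).
#' Feature sets are decided independently per subtype. Set
#' `median_filter = FALSE` for miRNA matrices, which are split but not
#' filtered.
#'
#' @param m an [expr_matrix] on the FPKM scale (the filter is defined on
#'   FPKM values, before any log transform).
#' @param labels data frame with columns `sample` and `subtype` covering
#'   all samples of `m`.
#' @param threshold median-FPKM removal threshold (default 0.7).
#' @param median_filter apply the median filter (default TRUE).
#' @return named list of per-subtype [expr_matrix] objects.
#' @export
subtype_expression_filter <- function(m, labels, threshold = 0.7,
                                      median_filter = TRUE) {
  stopifnot(inherits(m, "expr_matrix"),
            all(c("sample", "subtype") %in% names(labels)))
  if (m$scale != "fpkm") stop("the median-FPKM filter expects FPKM scale")
  lab <- labels$subtype[match(samples(m), labels$sample)]
  if (anyNA(lab)) stop("labels must cover all samples")
  lab <- factor(lab, levels = unique(labels$subtype))
  out <- lapply(split(samples(m), lab), function(ss) {
    if (length(ss) == 0) stop("subtype with zero samples")
    sub <- m$values[, ss, drop = FALSE]
    if (median_filter) {
      med <- apply(sub, 1, stats::median)
      sub <- sub[med > threshold, , drop = FALSE]
    }
    em_replace(m, sub)
  })
  out
}
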