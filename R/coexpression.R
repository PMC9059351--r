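#' Spearman rank correlation of two vectors
#'
#' Ties receive midranks and the coefficient is the Pearson correlation
#' of the rank vectors; on tie-free data this equals the classical
#' 1 - 6*sum(d^2)/(n(n^2-1)) form.
#'
#' @param x,y equal-length numeric vectors of at least 4 finite values.
#' @return the correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 4) stop("need at least 4 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: Spearman correlation is undefined",
         call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Fisher z-transformation of a Spearman coefficient
#'
#' Computes `F(rs) = 0.5 * ln((1 + rs) / (1 - rs))` and the z-score
#' `z = sqrt((n - 3) / 1.06) * F(rs)`; the 1.06 factor is the variance
#' correction appropriate for Spearman (rather than Pearson)
#' coefficients, so that z approximately follows a standard normal
#' distribution under the null.
#'
#' @param rs Spearman coefficient(s), strictly inside (-1, 1) unless
#'   `clip = TRUE`.
#' @param n sample size(s), at least 4.
#' @param clip if TRUE, coefficients at exactly +/-1 are clipped to
#'   `+/-(1 - eps)` with a message instead of raising an error.
#' @param eps clipping margin.
#' @return a list with numeric elements `fisher_f` and `z`.
#' @export
fisher_z <- function(rs, n, clip = FALSE, eps = 1e-7) {
  if (any(n < 4)) stop("`n` must be at least 4")
  if (any(abs(rs) > 1)) stop("`rs` must lie in [-1, 1]")
  at_one <- abs(rs) == 1
  if (any(at_one)) {
    if (!clip) {
      stop("|rs| = 1: Fisher transform diverges (set clip = TRUE to clip)",
           call. = FALSE)
    }
    message(sprintf("fisher_z: clipped %d coefficient(s) at |rs| = 1 to 1 - %g",
                    sum(at_one), eps))
    rs[at_one] <- sign(rs[at_one]) * (1 - eps)
  }
  f <- 0.5 * log((1 + rs) / (1 - rs))
  list(fisher_f = f, z = sqrt((n - 3) / 1.06) * f)
}

#' All cross-pair Spearman z-scores between two expression matrices
#'
#' Computes, over the shared samples of the two matrices, the Spearman
#' correlation and its Fisher z-score for every (feature of `a`,
#' feature of `b`) pair. This is the edge-candidate table from which
#' bipartite co-expression networks are thresholded.
#'
#' @param a,b [expr_matrix] objects of two different RNA classes sharing
#'   at least 4 sample IDs.
#' @param clip passed to [fisher_z()] for pairs with perfect rank
#'   agreement.
#' @return a `z_table`: data frame with columns `feature_a`, `class_a`,
#'   `feature_b`, `class_b`, `rs`, `z`, `n` (one row per cross pair; all
#'   rows share `n`).
#' @export
pairwise_z_table <- function(a, b, clip = FALSE) {
  stopifnot(inherits(a, "expr_matrix"), inherits(b, "expr_matrix"))
  shared <- intersect(samples(a), samples(b))
  if (length(shared) < 4) stop("fewer than 4 shared samples")
  va <- a$values[, shared, drop = FALSE]
  vb <- b$values[, shared, drop = FALSE]
  const_a <- apply(va, 1, function(r) stats::sd(r) == 0)
  const_b <- apply(vb, 1, function(r) stats::sd(r) == 0)
  if (any(const_a) || any(const_b)) {
    stop("constant feature(s) present; filter before correlating")
  }
  rs <- stats::cor(t(va), t(vb), method = "spearman")
  fz <- fisher_z(as.vector(rs), n = length(shared), clip = clip)
  out <- data.frame(
    feature_a = rep(rownames(rs), times = ncol(rs)),
    class_a = a$rna_class,
    feature_b = rep(colnames(rs), each = nrow(rs)),
    class_b = b$rna_class,
    rs = as.vector(rs),
    z = fz$z,
    n = length(shared),
    stringsAsFactors = FALSE
  )
  class(out) <- c("z_table", "data.frame")
  out
}

#' @rdname pairwise_z_table
#' @param z a `z_table`.
#' @param path file path for the tab-separated edge list.
#' @export
write_z_table <- function(z, path) {
  utils::write.table(z, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pairwise_z_table
#' @export
read_z_table <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("z_table", "data.frame")
  out
}
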