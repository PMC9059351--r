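#' Expression matrix container
#'
#' A thin S3 wrapper around a numeric features x samples matrix that keeps
#' track of the RNA class of its features (`"mRNA"`, `"lncRNA"` or
#' `"miRNA"`) and of the value scale (`"fpkm"` for non-negative
#' abundance-like values, `"log2"` after log transformation). All
#' preprocessing operations consume and return this container and refuse
#' inputs on the wrong scale.
#'
#' @param values numeric matrix, features as rows and samples as columns,
#'   with unique non-empty dimnames.
#' @param rna_class one of `"mRNA"`, `"lncRNA"`, `"miRNA"`.
#' @param scale `"fpkm"` or `"log2"`.
#'
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, rna_class = c("mRNA", "lncRNA", "miRNA"),
                        scale = c("fpkm", "log2")) {
  rna_class <- match.arg(rna_class)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (nrow(values) > 0 && is.null(rownames(values))) {
    stop("`values` must have feature rownames")
  }
  if (ncol(values) > 0 && is.null(colnames(values))) {
    stop("`values` must have sample colnames")
  }
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("feature and sample IDs must be unique")
  }
  if (scale == "fpkm" && any(values < 0, na.rm = TRUE)) {
    stop("negative values are not allowed on the FPKM scale")
  }
  structure(list(values = values, rna_class = rna_class, scale = scale),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %s, %s scale: %d features x %d samples\n",
              x$rna_class, x$scale, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Feature and sample identifiers of an expression matrix
#'
#' @param m an [expr_matrix].
#' @return character vector of IDs.
#' @export
features <- function(m) rownames(m$values)

#' @rdname features
#' @export
samples <- function(m) colnames(m$values)

# internal: rebuild with the same class/scale metadata
em_replace <- function(m, values, scale = m$scale) {
  expr_matrix(values, rna_class = m$rna_class, scale = scale)
}

#' Read / write expression matrices as tab-separated text
#'
#' The on-disk format is the pipeline's standard interchange: a header row
#' of sample IDs, one row per feature, tab-separated, with the feature ID
#' in the first column.
#'
#' @param path file path.
#' @param rna_class,scale metadata to attach on read (not stored in the
#'   file).
#' @return `read_expr_matrix` returns an [expr_matrix];
#'   `write_expr_matrix` returns `path` invisibly.
#' @export
read_expr_matrix <- function(path, rna_class, scale = "fpkm") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  expr_matrix(as.matrix(tab), rna_class = rna_class, scale = scale)
}

#' @rdname read_expr_matrix
#' @param m an [expr_matrix] to serialize.
#' @export
write_expr_matrix <- function(m, path) {
  df <- data.frame(feature = features(m), m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
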