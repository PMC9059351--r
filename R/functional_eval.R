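#' Fraction of node pairs supported by protein-protein interactions
#'
#' The percentage of the given unordered gene pairs that appear among
#' the PPI edges whose confidence score is strictly greater than
#' `score_min` (an edge scored exactly at the threshold does not
#' count).
#'
#' @param pairs data frame with columns `node_a`, `node_b`.
#' @param ppi_edges data frame with columns `gene_a`, `gene_b`,
#'   `score`.
#' @param score_min confidence threshold (default 0.95, strict `>`).
#' @return percentage in \[0, 100\].
#' @export
ppi_fraction <- function(pairs, ppi_edges, score_min = 0.95) {
  if (nrow(pairs) == 0) stop("empty pair list")
  hq <- ppi_edges[ppi_edges$score > score_min, , drop = FALSE]
  canon <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  100 * mean(canon(pairs$node_a, pairs$node_b) %in%
               canon(hq$gene_a, hq$gene_b))
}

#' Annotation probabilities and information content of ontology terms
#'
#' Propagates gene annotations to all ancestor terms, then computes for
#' each term `c` (per namespace) its annotation probability
#' `p(c)` — the fraction of annotated genes carrying `c` or a
#' descendant — and its information content `IC = -ln p(c)`. `p` is 1
#' at the root and non-decreasing from child to parent. Terms with no
#' propagated annotation are excluded (with a message).
#'
#' @param ont an [ontology].
#' @param annotations data frame `gene`, `term`, `namespace`.
#' @return an `ontology_stats` object: per namespace, a list with `p`,
#'   `ic` (named numeric vectors), `ancestors`, `gene_terms` (the
#'   propagated gene -> term list) and `n_genes`.
#' @export
information_content <- function(ont, annotations) {
  anc <- term_ancestors(ont)
  ns_of <- stats::setNames(ont$terms$namespace, ont$terms$id)
  out <- lapply(names(ont$roots), function(ns) {
    ann <- annotations[annotations$namespace == ns, , drop = FALSE]
    if (nrow(ann) == 0) return(NULL)
    per_gene <- lapply(split(ann$term, ann$gene), function(ts) {
      unique(unlist(anc[unique(ts)]))
    })
    # propagation can only reach terms of the same namespace by DAG
    # construction, but guard anyway
    per_gene <- lapply(per_gene, function(ts) ts[ns_of[ts] == ns])
    n_genes <- length(per_gene)
    counts <- table(unlist(per_gene))
    p <- as.numeric(counts) / n_genes
    names(p) <- names(counts)
    missing <- setdiff(ont$terms$id[ont$terms$namespace == ns], names(p))
    if (length(missing) > 0) {
      message(sprintf("information_content [%s]: %d term(s) without propagated annotations excluded",
                      ns, length(missing)))
    }
    list(p = p, ic = -log(p), ancestors = anc[names(p)],
         gene_terms = per_gene, n_genes = n_genes, root = ont$roots[[ns]])
  })
  names(out) <- names(ont$roots)
  structure(out[!vapply(out, is.null, TRUE)], class = "ontology_stats")
}

#' Relevance semantic similarity of two ontology terms
#'
#' Lin-style similarity weighted by how informative the common ancestor
#' is: over the common ancestors `c` of the two terms, the maximum of
#' `(2 ln p(c) / (ln p(t1) + ln p(t2))) * (1 - p(c))`. The factor
#' `1 - p(c)` sends the similarity to 0 whenever the only common
#' ancestor is the root (`p = 1`), and the score lives in \[0, 1).
#'
#' @param term1,term2 term IDs from the same namespace.
#' @param stats_ns the per-namespace element of an `ontology_stats`
#'   object (e.g. `stats$biological_process`).
#' @return similarity in \[0, 1).
#' @export
sim_rel <- function(term1, term2, stats_ns) {
  p <- stats_ns$p
  if (!(term1 %in% names(p)) || !(term2 %in% names(p))) {
    stop("term(s) not in this namespace's statistics")
  }
  common <- intersect(stats_ns$ancestors[[term1]], stats_ns$ancestors[[term2]])
  common <- common[common %in% names(p)]
  if (length(common) == 0) return(0)
  denom <- log(p[term1]) + log(p[term2])
  if (denom == 0) return(0)  # both terms are the root
  max(2 * log(p[common]) / denom * (1 - p[common]))
}

# sim_rel over all rows/cols of two term sets, vectorized via MICA search
sim_rel_matrix <- function(terms_a, terms_b, stats_ns) {
  outer(seq_along(terms_a), seq_along(terms_b),
        Vectorize(function(i, j) sim_rel(terms_a[i], terms_b[j], stats_ns)))
}

#' Gene-level functional similarity (funSim)
#'
#' Per namespace, the best-match average of [sim_rel()] between the two
#' genes' propagated term sets (mean of the row maxima and column
#' maxima of the pairwise term-similarity matrix); the funSim score is
#' the mean of the squared per-namespace scores over the namespaces
#' where both genes are annotated. Bounded in \[0, 1\].
#'
#' @param gene_a,gene_b gene IDs.
#' @param stats an `ontology_stats` from [information_content()].
#' @return funSim score in \[0, 1\].
#' @export
funsim <- function(gene_a, gene_b, stats) {
  ns_scores <- c()
  for (ns in names(stats)) {
    st <- stats[[ns]]
    ta <- st$gene_terms[[gene_a]]
    tb <- st$gene_terms[[gene_b]]
    if (is.null(ta) || is.null(tb)) next
    ta <- ta[ta %in% names(st$p)]
    tb <- tb[tb %in% names(st$p)]
    if (length(ta) == 0 || length(tb) == 0) next
    m <- sim_rel_matrix(ta, tb, st)
    ns_scores <- c(ns_scores,
                   (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2)
  }
  if (length(ns_scores) == 0) {
    stop("gene(s) without annotations in any namespace")
  }
  mean(ns_scores^2)
}

#' Per-area PPI support and functional similarity report
#'
#' For each area (A-D) and each association index, the percentage of
#' pairs with a high-confidence PPI and the mean pairwise funSim —
#' the benchmark contrasting coherent (area D) against incoherent
#' (area A) associations. Empty cells are reported as `NA`, not zero.
#'
#' @param records area-labeled mRNA-pair records from [assign_areas()].
#' @param ppi_edges scored PPI edge list (see [ppi_fraction()]).
#' @param stats optional `ontology_stats` for the funSim column.
#' @param score_min PPI confidence threshold.
#' @param max_pairs_funsim cap on pairs per cell for the funSim mean
#'   (sampled deterministically by order) to bound runtime.
#' @return data frame `index`, `area`, `n_pairs`, `ppi_pct`,
#'   `mean_funsim`.
#' @export
area_functional_report <- function(records, ppi_edges, stats = NULL,
                                   score_min = 0.95,
                                   max_pairs_funsim = 200) {
  grid <- expand.grid(index = unique(records$index),
                      area = c("A", "B", "C", "D"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- records[records$index == grid$index[i] &
                     !is.na(records$area) & records$area == grid$area[i], ,
                   drop = FALSE]
    n <- nrow(sel)
    ppi_pct <- if (n == 0) NA_real_ else ppi_fraction(sel, ppi_edges, score_min)
    mean_fs <- NA_real_
    if (!is.null(stats) && n > 0) {
      sub <- sel[seq_len(min(n, max_pairs_funsim)), , drop = FALSE]
      fs <- mapply(function(a, b) {
        tryCatch(funsim(a, b, stats), error = function(e) NA_real_)
      }, sub$node_a, sub$node_b)
      mean_fs <- mean(fs, na.rm = TRUE)
    }
    data.frame(index = grid$index[i], area = grid$area[i], n_pairs = n,
               ppi_pct = ppi_pct, mean_funsim = mean_fs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' mRNAs targeted by a lncRNA module
#'
#' The union of the bipartite mRNA neighborhoods of the module's
#' lncRNAs, optionally restricted to mRNAs connected to at least
#' `min_links` module members.
#'
#' @param module_lncrnas character vector of lncRNA IDs (non-empty).
#' @param net the lncRNA-mRNA `bipartite_network` (lncRNAs on the X
#'   side).
#' @param min_links minimum number of module lncRNAs an mRNA must
#'   connect to (default 1).
#' @return character vector of mRNA IDs.
#' @export
module_target_mrnas <- function(module_lncrnas, net, min_links = 1) {
  if (length(module_lncrnas) == 0) stop("empty module")
  present <- intersect(module_lncrnas, names(net$nbr_x))
  hits <- table(unlist(net$nbr_x[present]))
  sort(names(hits)[hits >= min_links])
}

#' Hypergeometric GO-term enrichment with BH correction
#'
#' Tests every term annotating the background (after propagating
#' annotations to ancestors) for over-representation in `gene_set`
#' using the one-sided hypergeometric upper tail, then adjusts across
#' tested terms with Benjamini-Hochberg.
#'
#' @param gene_set character vector, a subset of `background`.
#' @param background character vector of background gene IDs.
#' @param annotations data frame `gene`, `term`, `namespace`.
#' @param ont an [ontology].
#' @param namespace restrict to one namespace (default: all).
#' @return data frame `term`, `name`, `overlap`, `p`, `q`, sorted by
#'   increasing `p`.
#' @export
go_enrichment <- function(gene_set, background, annotations, ont,
                          namespace = NULL) {
  if (length(gene_set) == 0) stop("empty gene set")
  if (!all(gene_set %in% background)) stop("gene_set must be a subset of background")
  ann <- annotations[annotations$gene %in% background, , drop = FALSE]
  if (!is.null(namespace)) {
    ann <- ann[ann$namespace == namespace, , drop = FALSE]
  }
  anc <- term_ancestors(ont)
  per_gene <- lapply(split(ann$term, ann$gene), function(ts) {
    unique(unlist(anc[unique(ts)]))
  })
  long <- data.frame(gene = rep(names(per_gene), lengths(per_gene)),
                     term = unlist(per_gene), stringsAsFactors = FALSE)
  n_bg <- length(background)
  n_set <- length(gene_set)
  by_term <- split(long$gene, long$term)
  rows <- lapply(names(by_term), function(tid) {
    genes <- by_term[[tid]]
    k <- sum(gene_set %in% genes)
    data.frame(term = tid,
               name = ont$terms$name[match(tid, ont$terms$id)],
               overlap = k,
               p = stats::phyper(k - 1, length(genes), n_bg - length(genes),
                                 n_set, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster module enrichment profiles
#'
#' Keeps the terms significant (`q < 0.05`, strict) in at least one
#' module, transforms the q-value matrix to `-log10(q)` capped at
#' `cap`, and clusters the modules by agglomerative hierarchical
#' clustering (average linkage on Euclidean distances).
#'
#' @param q_matrix numeric matrix of FDR q-values, modules as rows,
#'   terms as columns.
#' @param k optional number of clusters to cut the dendrogram into.
#' @param q_max significance filter on terms (default 0.05).
#' @param cap upper cap on `-log10(q)` (default 10).
#' @return list with `hclust` (the dendrogram), `profile` (the
#'   filtered, transformed matrix) and `clusters` (named integer
#'   vector, NULL unless `k` given).
#' @export
cluster_enrichment_profiles <- function(q_matrix, k = NULL, q_max = 0.05,
                                        cap = 10) {
  if (nrow(q_matrix) < 2) stop("need at least 2 modules")
  keep <- apply(q_matrix, 2, function(col) any(col < q_max))
  if (!any(keep)) stop("no term passes the significance filter")
  x <- pmin(-log10(q_matrix[, keep, drop = FALSE]), cap)
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "average")
  clusters <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  list(hclust = hc, profile = x, clusters = clusters)
}
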