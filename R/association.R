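ASSOCIATION_METHODS <- c("jaccard", "simpson", "geometric", "cosine", "pcc")

#' Interaction-profile association index of two neighborhoods
#'
#' Quantifies how many Y-type partners two same-class nodes A and B
#' share in a bipartite network. With `i = |N(A) n N(B)|`,
#' `a = |N(A)|`, `b = |N(B)|` and `n_y` the total number of Y-type
#' nodes:
#' * jaccard:  `i / |N(A) u N(B)|`
#' * simpson:  `i / min(a, b)`
#' * geometric: `i^2 / (a * b)`
#' * cosine:   `i / sqrt(a * b)`
#' * pcc:      `(i * n_y - a * b) / sqrt(a * b * (n_y - a) * (n_y - b))`,
#'   the Pearson correlation of the two 0/1 incidence profiles over the
#'   Y node set.
#'
#' @param neighborhood_a,neighborhood_b character vectors of Y-type
#'   partner IDs.
#' @param method one of `"jaccard"`, `"simpson"`, `"geometric"`,
#'   `"cosine"`, `"pcc"`.
#' @param n_y total number of Y-type nodes (required for `"pcc"`).
#' @return the index value: in \[0, 1\] for the set-overlap indices, in
#'   \[-1, 1\] for `"pcc"`. Undefined combinations (an empty
#'   neighborhood for simpson/geometric/cosine/pcc, two empty sets for
#'   jaccard, or a full profile making pcc's denominator zero) raise a
#'   condition of class `undefined_index`.
#' @export
association_index <- function(neighborhood_a, neighborhood_b,
                              method = ASSOCIATION_METHODS, n_y = NULL) {
  method <- match.arg(method)
  a <- length(unique(neighborhood_a))
  b <- length(unique(neighborhood_b))
  i <- length(intersect(neighborhood_a, neighborhood_b))
  undef <- function(msg) stop(structure(
    class = c("undefined_index", "error", "condition"),
    list(message = msg, call = NULL)))
  if (method == "jaccard") {
    u <- length(union(neighborhood_a, neighborhood_b))
    if (u == 0) undef("jaccard undefined for two empty neighborhoods")
    return(i / u)
  }
  if (a == 0 || b == 0) undef(sprintf("%s undefined for an empty neighborhood", method))
  switch(method,
    simpson = i / min(a, b),
    geometric = i^2 / (a * b),
    cosine = i / sqrt(a * b),
    pcc = {
      if (is.null(n_y)) stop("`n_y` is required for method = \"pcc\"")
      if (n_y < max(a, b)) stop("`n_y` must be at least max(|N(A)|, |N(B)|)")
      den <- a * b * (n_y - a) * (n_y - b)
      if (den == 0) undef("pcc undefined when a profile covers all Y-type nodes")
      (i * n_y - a * b) / sqrt(den)
    })
}

#' All pairwise association indices on one side of a bipartite network
#'
#' Computes all five association indices for every unordered pair of
#' same-side nodes, via the incidence-matrix cross product (equivalent
#' to [association_index()] applied pairwise). Undefined values are
#' returned as `NA`.
#'
#' @param net a `bipartite_network`.
#' @param side `"x"` or `"y"`: which node set to compare (their shared
#'   partners live on the opposite side).
#' @return data frame with columns `node_a`, `node_b` (node_a < node_b)
#'   and one column per index.
#' @export
pairwise_profile_similarity <- function(net, side = c("x", "y")) {
  side <- match.arg(side)
  nodes <- if (side == "x") net$x_nodes else net$y_nodes
  partners <- if (side == "x") net$y_nodes else net$x_nodes
  if (length(nodes) < 2) stop("need at least 2 nodes on the chosen side")
  inc <- matrix(0L, nrow = length(nodes), ncol = length(partners),
                dimnames = list(nodes, partners))
  e <- net$edges
  if (side == "x") inc[cbind(e$x, e$y)] <- 1L else inc[cbind(e$y, e$x)] <- 1L
  ov <- inc %*% t(inc)              # pairwise intersection sizes
  deg <- diag(ov)
  n_y <- length(partners)
  ut <- which(upper.tri(ov), arr.ind = TRUE)
  ia <- ut[, 1]; ib <- ut[, 2]
  i <- ov[ut]
  a <- deg[ia]; b <- deg[ib]
  u <- a + b - i
  pcc_den <- a * b * (n_y - a) * (n_y - b)
  out <- data.frame(
    node_a = nodes[ia], node_b = nodes[ib],
    jaccard = ifelse(u > 0, i / u, NA_real_),
    simpson = ifelse(pmin(a, b) > 0, i / pmin(a, b), NA_real_),
    geometric = ifelse(a * b > 0, i^2 / (a * b), NA_real_),
    cosine = ifelse(a * b > 0, i / sqrt(a * b), NA_real_),
    pcc = ifelse(pcc_den > 0, (i * n_y - a * b) / sqrt(pcc_den), NA_real_),
    stringsAsFactors = FALSE
  )
  out[order(out$node_a, out$node_b), , drop = FALSE]
}

#' Merge per-context similarities into two-context similarity records
#'
#' The coherence analysis asks whether node pairs with similar
#' interaction profiles in one bipartite context (say, shared mRNAs)
#' are also similar in another (shared miRNAs). This joins the two
#' per-context tables into long-format records, one row per (pair,
#' index), keeping pairs present in both contexts.
#'
#' @param sim1,sim2 data frames from [pairwise_profile_similarity()]
#'   computed on the same node class in two different bipartite
#'   networks.
#' @return data frame with columns `node_a`, `node_b`, `index`,
#'   `value_1`, `value_2`.
#' @export
similarity_records <- function(sim1, sim2) {
  merged <- merge(sim1, sim2, by = c("node_a", "node_b"),
                  suffixes = c("_1", "_2"))
  recs <- do.call(rbind, lapply(ASSOCIATION_METHODS, function(m) {
    data.frame(node_a = merged$node_a, node_b = merged$node_b, index = m,
               value_1 = merged[[paste0(m, "_1")]],
               value_2 = merged[[paste0(m, "_2")]],
               stringsAsFactors = FALSE)
  }))
  rownames(recs) <- NULL
  recs
}

#' Assign quadrant areas on the two-context similarity map
#'
#' For each index, the `area_quantile` quantile of each context's
#' values defines its high/low boundary; records are then labeled
#' A = low/low, B = high/low, C = low/high, D = high/high ("high" means
#' at or above the boundary, so ties at the boundary — common for
#' set-overlap indices saturating at 1 — count as high, matching the
#' top-fraction rule of [select_coherent_pairs()]). Records with a
#' missing value in either
#' context stay unlabeled (`NA`).
#'
#' @param records data frame from [similarity_records()].
#' @param area_quantile per-axis quantile for the high/low boundary
#'   (default 0.95).
#' @return `records` with an added `area` column.
#' @export
assign_areas <- function(records, area_quantile = 0.95) {
  records$area <- NA_character_
  for (m in unique(records$index)) {
    sel <- records$index == m
    v1 <- records$value_1[sel]; v2 <- records$value_2[sel]
    ok <- !is.na(v1) & !is.na(v2)
    if (!any(ok)) next
    if (stats::sd(v1[ok]) == 0 || stats::sd(v2[ok]) == 0) {
      stop("degenerate axis (all values equal) for index ", m)
    }
    t1 <- stats::quantile(v1[ok], area_quantile, names = FALSE)
    t2 <- stats::quantile(v2[ok], area_quantile, names = FALSE)
    hi1 <- v1 >= t1; hi2 <- v2 >= t2
    lab <- ifelse(hi1 & hi2, "D", ifelse(hi1, "B", ifelse(hi2, "C", "A")))
    lab[!ok] <- NA_character_
    records$area[sel] <- lab
  }
  records
}

#' Coherence selection configuration
#'
#' @param min_indices number of supporting indices required (1-5,
#'   default 3).
#' @param top_frac extreme-rank fraction per index and axis (default
#'   0.0005, i.e. the top 0.05 percent).
#' @param area_quantile high/low boundary quantile for [assign_areas()].
#' @return a validated `coherence_config` list.
#' @export
coherence_config <- function(min_indices = 3, top_frac = 0.0005,
                             area_quantile = 0.95) {
  stopifnot(min_indices >= 1, min_indices <= 5,
            top_frac > 0, top_frac < 1,
            area_quantile > 0, area_quantile < 1)
  structure(list(min_indices = min_indices, top_frac = top_frac,
                 area_quantile = area_quantile),
            class = "coherence_config")
}

#' Select coherent node pairs by multi-index consensus
#'
#' A pair supports coherence under one index when it is labeled area D
#' and both of its context values reach the top `top_frac` fraction of
#' that index/axis distribution (value at or above the
#' `1 - top_frac` quantile). Pairs supported by at least `min_indices`
#' of the five indices are coherent. Missing index values never qualify
#' a pair.
#'
#' @param records area-labeled records from [assign_areas()].
#' @param config a [coherence_config()].
#' @return data frame `node_a`, `node_b`, `n_support`, sorted by
#'   decreasing support; possibly zero rows.
#' @export
select_coherent_pairs <- function(records, config = coherence_config()) {
  if (is.null(records$area)) stop("assign areas before selecting coherent pairs")
  support <- rep(0L, nrow(records))
  for (m in unique(records$index)) {
    sel <- which(records$index == m)
    v1 <- records$value_1[sel]; v2 <- records$value_2[sel]
    ok <- !is.na(v1) & !is.na(v2)
    if (!any(ok)) next
    t1 <- stats::quantile(v1[ok], 1 - config$top_frac, names = FALSE)
    t2 <- stats::quantile(v2[ok], 1 - config$top_frac, names = FALSE)
    hit <- ok & records$area[sel] == "D" & v1 >= t1 & v2 >= t2
    hit[is.na(hit)] <- FALSE
    support[sel][hit] <- 1L
  }
  key <- paste(records$node_a, records$node_b, sep = "\r")
  n_support <- tapply(support, key, sum)
  pairs <- do.call(rbind, strsplit(names(n_support), "\r", fixed = TRUE))
  out <- data.frame(node_a = pairs[, 1], node_b = pairs[, 2],
                    n_support = as.integer(n_support),
                    stringsAsFactors = FALSE)
  out <- out[out$n_support >= config$min_indices, , drop = FALSE]
  out <- out[order(-out$n_support, out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
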