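#' Scale-free topology fit of a degree sequence
#'
#' Forms the empirical degree distribution p(k) (the fraction of nodes
#' with degree k, over the distinct observed positive degrees) and
#' regresses log10 p(k) on log10 k by ordinary least squares. A network
#' close to scale-free yields a high R-squared with a negative slope.
#'
#' @param degrees integer vector of node degrees (positive).
#' @return a `scale_free_fit` list with `r_squared`, `slope`, and the
#'   degree histogram (`k`, `p_k`).
#' @export
scale_free_fit <- function(degrees) {
  degrees <- degrees[degrees > 0]
  tab <- table(degrees)
  k <- as.numeric(names(tab))
  if (length(k) < 3) {
    stop(structure(
      class = c("degenerate_fit", "error", "condition"),
      list(message = "fewer than 3 distinct positive degrees: scale-free fit is degenerate",
           call = NULL)))
  }
  p_k <- as.numeric(tab) / sum(tab)
  fit <- stats::lm(log10(p_k) ~ log10(k))
  res <- stats::residuals(fit)
  ly <- log10(p_k)
  r2 <- 1 - sum(res^2) / sum((ly - mean(ly))^2)
  structure(list(
    r_squared = r2,
    slope = unname(stats::coef(fit)[2]),
    k = k, p_k = p_k
  ), class = "scale_free_fit")
}

#' @export
print.scale_free_fit <- function(x, ...) {
  cat(sprintf("<scale_free_fit> R^2 = %.3f, slope = %.3f over %d distinct degrees\n",
              x$r_squared, x$slope, length(x$k)))
  if (!is.null(x$cutoff)) cat(sprintf("  selected |z| cutoff: %.4f\n", x$cutoff))
  invisible(x)
}

# degrees of all nodes with >= 1 edge at a given |z| cutoff
threshold_degrees <- function(z_table, cutoff) {
  keep <- abs(z_table$z) >= cutoff
  c(table(z_table$feature_a[keep]), table(z_table$feature_b[keep]))
}

#' Select a |z| cutoff by the scale-free topology criterion
#'
#' Scans a grid of candidate |z| cutoffs (by default 50 evenly spaced
#' quantiles of |z|), evaluates the scale-free fit of the thresholded
#' network at each, and keeps candidates with R-squared above `r2_min`
#' and regression slope inside `slope_range`. Among passing cutoffs the
#' smallest is returned, i.e. the densest admissible network: fits with
#' R-squared close to 1 at high cutoffs tend to describe networks with
#' very few connections. Degrees pool both node types.
#'
#' @param z_table a `z_table` from [pairwise_z_table()].
#' @param grid optional numeric vector of candidate cutoffs; default 50
#'   evenly spaced quantiles of `|z|`.
#' @param r2_min minimum fit index (default 0.8, strict `>`).
#' @param slope_range open interval for the slope (default (-2, -0.5)).
#' @param n_grid grid size when `grid` is NULL.
#' @return a `scale_free_fit` augmented with `cutoff` and `scan` (a data
#'   frame with one row per candidate: cutoff, edge count, R-squared,
#'   slope, pass flag).
#' @export
select_cutoff <- function(z_table, grid = NULL, r2_min = 0.8,
                          slope_range = c(-2, -0.5), n_grid = 50) {
  az <- abs(z_table$z)
  if (is.null(grid)) {
    grid <- unique(stats::quantile(az, probs = seq_len(n_grid) / (n_grid + 1),
                                   names = FALSE))
  }
  grid <- sort(grid)
  scan <- data.frame(cutoff = grid, edges = NA_integer_,
                     r_squared = NA_real_, slope = NA_real_, pass = FALSE)
  fits <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    scan$edges[i] <- sum(az >= grid[i])
    fit <- tryCatch(scale_free_fit(threshold_degrees(z_table, grid[i])),
                    degenerate_fit = function(e) NULL)
    if (is.null(fit)) next
    fits[[i]] <- fit
    scan$r_squared[i] <- fit$r_squared
    scan$slope[i] <- fit$slope
    scan$pass[i] <- fit$r_squared > r2_min &&
      fit$slope > slope_range[1] && fit$slope < slope_range[2]
  }
  if (!any(scan$pass)) {
    cond <- structure(
      class = c("no_cutoff", "error", "condition"),
      list(message = "no candidate cutoff satisfies the scale-free topology criterion",
           call = NULL, scan = scan))
    stop(cond)
  }
  i <- which(scan$pass)[1]
  fit <- fits[[i]]
  fit$cutoff <- grid[i]
  fit$scan <- scan
  fit
}

#' Build a bipartite co-expression network from a z-table
#'
#' Keeps every cross-class pair whose `|z|` is greater than or equal to
#' the cutoff (the boundary is included), then removes sparsely
#' connected nodes (degree below `min_degree`; with the default 1 this
#' drops isolated nodes only). Edges retain their signed z-value.
#'
#' @param z_table a `z_table`.
#' @param cutoff the |z| threshold, typically from [select_cutoff()].
#' @param min_degree minimum post-threshold node degree (default 1).
#' @return a `bipartite_network`: list with `edges` (data frame `x`,
#'   `y`, `z`), node vectors `x_nodes` / `y_nodes`, their RNA classes,
#'   neighborhood lists `nbr_x` / `nbr_y`, and `n_y = length(y_nodes)`.
#' @export
build_bipartite <- function(z_table, cutoff, min_degree = 1) {
  keep <- abs(z_table$z) >= cutoff
  edges <- data.frame(x = z_table$feature_a[keep],
                      y = z_table$feature_b[keep],
                      z = z_table$z[keep], stringsAsFactors = FALSE)
  if (min_degree > 0 && nrow(edges) > 0) {
    # one pass: degrees evaluated on the thresholded network
    deg_x <- table(edges$x)
    deg_y <- table(edges$y)
    ok <- deg_x[edges$x] >= min_degree & deg_y[edges$y] >= min_degree
    edges <- edges[as.vector(ok), , drop = FALSE]
  }
  if (nrow(edges) == 0) stop("empty network after thresholding and degree filtering")
  net <- structure(list(
    edges = edges,
    x_nodes = sort(unique(edges$x)),
    y_nodes = sort(unique(edges$y)),
    x_class = z_table$class_a[1],
    y_class = z_table$class_b[1],
    cutoff = cutoff
  ), class = "bipartite_network")
  net$nbr_x <- lapply(split(edges$y, factor(edges$x, levels = net$x_nodes)), unique)
  net$nbr_y <- lapply(split(edges$x, factor(edges$y, levels = net$y_nodes)), unique)
  net$n_y <- length(net$y_nodes)
  net
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network> %s (%d) x %s (%d), %d edges, |z| >= %.3f\n",
              x$x_class, length(x$x_nodes), x$y_class, length(x$y_nodes),
              nrow(x$edges), x$cutoff))
  invisible(x)
}

#' Neighborhood of a node in a bipartite network
#'
#' @param net a `bipartite_network`.
#' @param node node identifier.
#' @param side `"x"` or `"y"`, the side `node` belongs to.
#' @return character vector of the node's partners on the other side.
#' @export
neighborhood <- function(net, node, side = c("x", "y")) {
  side <- match.arg(side)
  nbrs <- if (side == "x") net$nbr_x else net$nbr_y
  if (!node %in% names(nbrs)) stop("node not in network: ", node)
  nbrs[[node]]
}

#' Serialize a bipartite network
#'
#' Writes the edge list as tab-separated `(node_x, node_y, z)` and, next
#' to it, a node attribute table `(node, class, degree)`.
#'
#' @param net a `bipartite_network`.
#' @param path edge-list file path; the node table goes to
#'   `<path>.nodes`.
#' @export
write_bipartite <- function(net, path) {
  utils::write.table(
    data.frame(node_x = net$edges$x, node_y = net$edges$y, z = net$edges$z),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  nodes <- data.frame(
    node = c(net$x_nodes, net$y_nodes),
    class = c(rep(net$x_class, length(net$x_nodes)),
              rep(net$y_class, length(net$y_nodes))),
    degree = c(lengths(net$nbr_x)[net$x_nodes], lengths(net$nbr_y)[net$y_nodes]))
  utils::write.table(nodes, paste0(path, ".nodes"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
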