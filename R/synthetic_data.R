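#' Configuration for a synthetic multi-subtype ceRNA cohort
#'
#' Describes a cohort in which groups of mRNAs and lncRNAs are
#' positively co-expressed with one another and negatively co-expressed
#' with the miRNAs of their group — the competing-endogenous-RNA
#' pattern the pipeline is designed to detect. Defaults describe a
#' compact two-condition cohort of 200 samples with five planted
#' groups of heterogeneous size (regulatory modules in real
#' transcriptomes vary widely in size, and the size spread is what
#' gives thresholded networks a broad degree distribution).
#'
#' @param n_subtypes number of subtypes; subtypes differ by which
#'   planted groups are active.
#' @param samples_per_subtype samples per subtype.
#' @param n_mrna,n_lncrna,n_mirna class totals.
#' @param n_groups number of planted ceRNA groups.
#' @param group_sizes list with numeric vectors `mrna`, `lncrna`,
#'   `mirna` of per-group member counts (scalars are recycled to
#'   `n_groups`); per-class sums must not exceed the class totals.
#' @param loading effect size beta of the latent group activity on its
#'   members (each member's actual loading is beta scaled by a fixed
#'   Uniform(0.5, 1) affinity multiplier).
#' @param noise_sd standard deviation of the additive log-scale noise.
#' @param zero_rate fraction of entries zeroed completely at random.
#' @param low_expr_frac fraction of background features given a low
#'   baseline so the median-FPKM filter has work to do.
#' @param seed integer RNG seed.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_subtypes = 2, samples_per_subtype = 100,
                             n_mrna = 300, n_lncrna = 150, n_mirna = 60,
                             n_groups = 5,
                             group_sizes = list(mrna = c(20, 14, 10, 7, 5),
                                                lncrna = c(12, 8, 6, 4, 3),
                                                mirna = c(6, 4, 3, 3, 2)),
                             loading = 1.2, noise_sd = 1, zero_rate = 0.05,
                             low_expr_frac = 0.1, seed = 42) {
  counts <- c(n_subtypes, samples_per_subtype, n_mrna, n_lncrna, n_mirna,
              n_groups)
  if (any(counts < 0)) stop("all counts must be non-negative")
  if (!(zero_rate >= 0 && zero_rate <= 1)) stop("`zero_rate` must be in [0, 1]")
  if (n_groups > 0) {
    gs <- lapply(group_sizes[c("mrna", "lncrna", "mirna")], function(v) {
      if (length(v) == 1) v <- rep(v, n_groups)
      if (length(v) != n_groups) stop("group size vectors must have length n_groups")
      v
    })
  } else {
    gs <- list(mrna = integer(0), lncrna = integer(0), mirna = integer(0))
  }
  totals <- c(mrna = n_mrna, lncrna = n_lncrna, mirna = n_mirna)
  for (cl in names(gs)) {
    if (sum(gs[[cl]]) > totals[[cl]]) {
      stop("group sizes exceed class total for ", cl)
    }
  }
  structure(list(
    n_subtypes = n_subtypes, samples_per_subtype = samples_per_subtype,
    n_mrna = n_mrna, n_lncrna = n_lncrna, n_mirna = n_mirna,
    n_groups = n_groups, group_sizes = gs, loading = loading,
    noise_sd = noise_sd, zero_rate = zero_rate,
    low_expr_frac = low_expr_frac, seed = seed
  ), class = "synthetic_config")
}

# group membership vector for one class: g for members, 0 for background
assign_groups <- function(n_features, sizes) {
  g <- integer(n_features)
  if (length(sizes) > 0 && sum(sizes) > 0) {
    g[seq_len(sum(sizes))] <- rep(seq_along(sizes), sizes)
  }
  g
}

#' Generate a synthetic cohort with planted ceRNA groups
#'
#' Per sample, each planted group active in the sample's subtype has a
#' latent activity `a ~ N(0, 1)`; member mRNAs and lncRNAs receive
#' `+beta * u * a` and member miRNAs `-beta * u * a` (with `u` a fixed
#' per-member affinity in \[0.5, 1\]) plus Gaussian noise, on the log2
#' scale. Background features are pure noise. Values are exponentiated
#' to an FPKM-like positive scale around a per-feature baseline (a
#' `low_expr_frac` fraction of background features get a low baseline),
#' and zeros are injected completely at random at `zero_rate`.
#' Subtype 1 has all groups active; each later subtype drops one more
#' of the highest-numbered groups, creating subtype-specific structure.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_cohort` list: `matrices` (named list of three
#'   FPKM-scale [expr_matrix] objects), `labels` (data frame `sample`,
#'   `subtype`), `biotypes` (data frame `feature`, `biotype`; lncRNAs
#'   alternate lincRNA/antisense) and `truth` (feature -> group map,
#'   per-subtype active groups, expected correlation signs, affinity
#'   multipliers).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    n_samp <- config$n_subtypes * config$samples_per_subtype
    samp <- sprintf("S%04d", seq_len(max(n_samp, 1)))[seq_len(n_samp)]
    subtype <- rep(sprintf("subtype%d", seq_len(config$n_subtypes)),
                   each = config$samples_per_subtype)
    ids <- list(mrna = sprintf("MR%04d", seq_len(config$n_mrna)),
                lncrna = sprintf("LNC%04d", seq_len(config$n_lncrna)),
                mirna = sprintf("MIR%04d", seq_len(config$n_mirna)))
    grp <- lapply(c(mrna = "mrna", lncrna = "lncrna", mirna = "mirna"),
                  function(cl) {
                    stats::setNames(
                      assign_groups(length(ids[[cl]]), config$group_sizes[[cl]]),
                      ids[[cl]])
                  })
    sign_of <- c(mrna = 1, lncrna = 1, mirna = -1)
    active <- lapply(seq_len(config$n_subtypes), function(s) {
      if (config$n_groups == 0) return(integer(0))
      seq_len(max(config$n_groups - (s - 1), 1))
    })
    names(active) <- sprintf("subtype%d", seq_len(config$n_subtypes))
    # latent group activities, one per group x sample; a group contributes
    # only in subtypes where it is active
    a <- matrix(stats::rnorm(config$n_groups * n_samp),
                nrow = max(config$n_groups, 1), ncol = max(n_samp, 1))
    if (config$n_groups > 0 && n_samp > 0) {
      for (s in seq_len(config$n_subtypes)) {
        cols <- which(subtype == sprintf("subtype%d", s))
        off <- setdiff(seq_len(config$n_groups), active[[s]])
        a[off, cols] <- 0
      }
    }
    mult <- lapply(grp, function(g) {
      u <- stats::runif(length(g), 0.5, 1)
      u[g == 0] <- 0
      stats::setNames(u, names(g))
    })
    mats <- lapply(c(mrna = "mrna", lncrna = "lncrna", mirna = "mirna"),
                   function(cl) {
      nf <- length(ids[[cl]])
      if (nf == 0 || n_samp == 0) {
        return(matrix(numeric(0), nrow = nf, ncol = n_samp,
                      dimnames = list(ids[[cl]], samp)))
      }
      x <- matrix(stats::rnorm(nf * n_samp, sd = config$noise_sd),
                  nrow = nf, dimnames = list(ids[[cl]], samp))
      g <- grp[[cl]]
      member <- which(g > 0)
      if (length(member) > 0) {
        x[member, ] <- x[member, , drop = FALSE] +
          sign_of[[cl]] * config$loading * mult[[cl]][member] *
          a[g[member], , drop = FALSE]
      }
      # per-feature baselines; some background features are lowly expressed
      mu <- stats::rnorm(nf, mean = 3, sd = 1)
      bg <- which(g == 0)
      n_low <- floor(length(bg) * config$low_expr_frac)
      if (n_low > 0) {
        mu[bg[seq_len(n_low)]] <- stats::rnorm(n_low, mean = -2, sd = 1)
      }
      fpkm <- 2^(x + mu)
      if (config$zero_rate > 0) {
        fpkm[stats::runif(length(fpkm)) < config$zero_rate] <- 0
      }
      fpkm
    })
    biotype <- data.frame(
      feature = c(ids$mrna, ids$lncrna),
      biotype = c(rep("protein_coding", length(ids$mrna)),
                  rep_len(c("lincRNA", "antisense"),
                          length(ids$lncrna))[seq_len(length(ids$lncrna))]),
      stringsAsFactors = FALSE)
    structure(list(
      matrices = list(
        mRNA = expr_matrix(mats$mrna, "mRNA", "fpkm"),
        lncRNA = expr_matrix(mats$lncrna, "lncRNA", "fpkm"),
        miRNA = expr_matrix(mats$mirna, "miRNA", "fpkm")),
      labels = data.frame(sample = samp, subtype = subtype,
                          stringsAsFactors = FALSE),
      biotypes = biotype,
      truth = list(group_of = grp, active_groups = active,
                   signs = sign_of, affinity = mult)
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples, %d subtype(s); mRNA %d, lncRNA %d, miRNA %d\n",
              nrow(x$labels), length(unique(x$labels$subtype)),
              nrow(x$matrices$mRNA$values), nrow(x$matrices$lncRNA$values),
              nrow(x$matrices$miRNA$values)))
  invisible(x)
}

#' Toy ontology and annotations matched to planted groups
#'
#' Builds, for the biological-process and molecular-function
#' namespaces, a small single-rooted DAG: a root, two intermediate
#' branches, one term per planted group annotating exactly that group's
#' mRNA members, and one broad background term per branch annotating
#' every third background mRNA. Every mRNA is also annotated to the
#' root, so genes in the same planted group share at least one
#' specific term while background genes mostly meet only at the root.
#' Construction is deterministic given the ground truth.
#'
#' @param cohort a `synthetic_cohort` (or its `truth` element).
#' @return list with `ontology` (an [ontology]) and `annotations`
#'   (data frame `gene`, `term`, `namespace`).
#' @export
generate_toy_ontology <- function(cohort) {
  truth <- if (inherits(cohort, "synthetic_cohort")) cohort$truth else cohort
  g <- truth$group_of$mrna
  genes <- names(g)
  groups <- sort(unique(g[g > 0]))
  ns_defs <- list(biological_process = "BP", molecular_function = "MF")
  terms <- list(); parents <- list(); ann <- list()
  for (ns in names(ns_defs)) {
    pre <- ns_defs[[ns]]
    root <- sprintf("%s:0000000", pre)
    branch <- sprintf("%s:0000%03d", pre, 1:2)
    terms[[ns]] <- data.frame(
      id = c(root, branch,
             sprintf("%s:001%03d", pre, groups),
             sprintf("%s:002%03d", pre, 1:2)),
      name = c(sprintf("%s root", ns),
               paste(ns, "branch", 1:2),
               sprintf("%s group-%d program", ns, groups),
               paste(ns, "background process", 1:2)),
      namespace = ns, stringsAsFactors = FALSE)
    p <- c(list(character(0)), list(root), list(root),
           as.list(branch[(groups %% 2) + 1]),
           as.list(branch))
    names(p) <- terms[[ns]]$id
    parents <- c(parents, p)
    grp_term <- stats::setNames(sprintf("%s:001%03d", pre, groups), groups)
    bg_term <- sprintf("%s:002%03d", pre, 1:2)
    bg_genes <- genes[g == 0]
    bg_pick <- bg_genes[seq_along(bg_genes) %% 3 == 0]
    ann[[ns]] <- data.frame(
      gene = c(genes,
               names(g)[g > 0],
               bg_pick),
      term = c(rep(root, length(genes)),
               grp_term[as.character(g[g > 0])],
               rep_len(bg_term, length(bg_pick))),
      namespace = ns, stringsAsFactors = FALSE)
  }
  all_terms <- do.call(rbind, terms)
  rownames(all_terms) <- NULL
  list(ontology = ontology(all_terms, parents),
       annotations = do.call(rbind, c(ann, list(make.row.names = FALSE))))
}

#' Toy scored protein-protein interaction list
#'
#' Connects same-group mRNA pairs with probability `p_within` and all
#' other mRNA pairs with probability `p_between`; every realized edge
#' carries a confidence score drawn uniformly from \[0.9, 1\].
#'
#' @param cohort a `synthetic_cohort` (or its `truth` element).
#' @param p_within,p_between connection probabilities,
#'   `0 <= p_between <= p_within <= 1`.
#' @param seed RNG seed.
#' @return data frame `gene_a`, `gene_b`, `score`.
#' @export
generate_toy_ppi <- function(cohort, p_within = 0.8, p_between = 0.01,
                             seed = 1) {
  truth <- if (inherits(cohort, "synthetic_cohort")) cohort$truth else cohort
  if (!(p_between >= 0 && p_between <= p_within && p_within <= 1)) {
    stop("need 0 <= p_between <= p_within <= 1")
  }
  g <- truth$group_of$mrna
  genes <- names(g)
  withr::with_seed(seed, {
    idx <- utils::combn(length(genes), 2)
    same <- g[idx[1, ]] > 0 & g[idx[1, ]] == g[idx[2, ]]
    prob <- ifelse(same, p_within, p_between)
    keep <- stats::runif(length(prob)) < prob
    data.frame(gene_a = genes[idx[1, keep]],
               gene_b = genes[idx[2, keep]],
               score = stats::runif(sum(keep), 0.9, 1),
               stringsAsFactors = FALSE)
  })
}

#' Write a synthetic cohort in the pipeline's input formats
#'
#' Emits tab-separated expression matrices (`matrix_mrna.tsv`,
#' `matrix_lncrna.tsv`, `matrix_mirna.tsv`), the sample-to-subtype
#' label table (`labels.tsv`) and the feature biotype table
#' (`biotypes.tsv`) into `dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    mrna = file.path(dir, "matrix_mrna.tsv"),
    lncrna = file.path(dir, "matrix_lncrna.tsv"),
    mirna = file.path(dir, "matrix_mirna.tsv"),
    labels = file.path(dir, "labels.tsv"),
    biotypes = file.path(dir, "biotypes.tsv"))
  write_expr_matrix(cohort$matrices$mRNA, paths[["mrna"]])
  write_expr_matrix(cohort$matrices$lncRNA, paths[["lncrna"]])
  write_expr_matrix(cohort$matrices$miRNA, paths[["mirna"]])
  utils::write.table(cohort$labels, paths[["labels"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$biotypes, paths[["biotypes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
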