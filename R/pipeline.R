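#' End-to-end pipeline configuration
#'
#' Bundles the input file paths and every stage parameter of the
#' subtype-stratified workflow. Defaults mirror the method's stated
#' values: 80% non-zero filter, median-FPKM threshold 0.7, scale-free
#' criterion R-squared > 0.8 with slope in (-2, -0.5), coherence
#' consensus of >= 3 indices in the top 0.05 percent.
#'
#' @param mrna,lncrna,mirna paths to FPKM-scale expression matrices
#'   (tab-separated, features x samples).
#' @param labels path to the two-column sample/subtype table.
#' @param ppi optional path to a scored PPI list (`gene_a`, `gene_b`,
#'   `score`).
#' @param obo,annotations optional paths to an OBO ontology and a
#'   gene/term/namespace annotation table.
#' @param out_dir output directory for all result tables and the run
#'   manifest.
#' @param min_frac,median_threshold,k_sd preprocessing parameters.
#' @param r2_min,slope_range,min_degree network-construction
#'   parameters.
#' @param area_quantile,min_indices,top_frac coherence parameters.
#' @param min_size,seed module-detection parameters.
#' @param ppi_score_min PPI confidence threshold.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(mrna, lncrna, mirna, labels, out_dir,
                            ppi = NULL, obo = NULL, annotations = NULL,
                            min_frac = 0.8, median_threshold = 0.7,
                            k_sd = 2, r2_min = 0.8,
                            slope_range = c(-2, -0.5), min_degree = 1,
                            area_quantile = 0.95, min_indices = 3,
                            top_frac = 0.0005, min_size = 3, seed = 1,
                            ppi_score_min = 0.95) {
  paths <- c(mrna = mrna, lncrna = lncrna, mirna = mirna, labels = labels,
             ppi = ppi, obo = obo, annotations = annotations)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  structure(list(
    paths = as.list(paths), out_dir = out_dir, min_frac = min_frac,
    median_threshold = median_threshold, k_sd = k_sd, r2_min = r2_min,
    slope_range = slope_range, min_degree = min_degree,
    area_quantile = area_quantile, min_indices = min_indices,
    top_frac = top_frac, min_size = min_size, seed = seed,
    ppi_score_min = ppi_score_min
  ), class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the stratified ceRNA-network workflow end to end
#'
#' Per subtype: preprocesses the three class matrices, computes the
#' three cross-class Fisher-z tables, selects |z| cutoffs by the
#' scale-free criterion, builds the bipartite networks, scores lncRNA
#' pairs with the five association indices in the shared-mRNA and
#' shared-miRNA contexts, assigns areas, selects coherent pairs,
#' builds the coherent association network and detects its modules.
#' When an ontology/annotation pair and/or a PPI list are configured,
#' per-module GO enrichment and the per-area functional report are
#' added. A class-pair network for which no cutoff satisfies the
#' scale-free criterion is recorded as a warning and skipped; the run
#' continues with the remaining networks (a cohort without planted
#' signal thus completes with empty coherent networks).
#'
#' All tables are written under `config$out_dir` with fixed names
#' (`ztable_<pair>_<subtype>.tsv`, `network_<pair>_<subtype>.tsv`,
#' `similarity_lncRNA_<subtype>.tsv`, `coherent_<subtype>.tsv`,
#' `modules_<subtype>.tsv`, `enrichment_<subtype>_m<k>.tsv`,
#' `manifest.json`).
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (also written as JSON), invisibly: package
#'   version, parameter echo, per-stage before/after counts, selected
#'   cutoffs, warnings, and MD5 checksums of every written table.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "lnccan",
    version = as.character(utils::packageVersion("lnccan")),
    parameters = config[setdiff(names(config), "paths")],
    inputs = config$paths, stages = list(), subtypes = list(),
    warnings = character(0))
  note <- function(msg) {
    manifest$warnings <<- c(manifest$warnings, msg)
    warning(msg, call. = FALSE)
  }

  raw <- list(
    mRNA = read_expr_matrix(config$paths$mrna, "mRNA"),
    lncRNA = read_expr_matrix(config$paths$lncrna, "lncRNA"),
    miRNA = read_expr_matrix(config$paths$mirna, "miRNA"))
  labels <- utils::read.table(config$paths$labels, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)

  # cohort-level: non-zero filter, upper-quartile normalization
  norm <- lapply(raw, function(m) {
    upper_quartile_normalize(filter_nonzero_features(m, config$min_frac))
  })
  manifest$stages$nonzero_filter <- lapply(norm, function(m) {
    list(features = nrow(m$values))
  })

  # subtype split on the FPKM scale; median filter for mRNA/lncRNA only
  split_m <- list(
    mRNA = subtype_expression_filter(norm$mRNA, labels,
                                     config$median_threshold),
    lncRNA = subtype_expression_filter(norm$lncRNA, labels,
                                       config$median_threshold),
    miRNA = subtype_expression_filter(norm$miRNA, labels,
                                      median_filter = FALSE))
  subtypes <- names(split_m$mRNA)

  ppi <- if (!is.null(config$paths$ppi)) {
    utils::read.table(config$paths$ppi, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  ont <- if (!is.null(config$paths$obo)) read_obo(config$paths$obo)
  ann <- if (!is.null(config$paths$annotations)) {
    read_annotations(config$paths$annotations)
  }
  stats_ns <- if (!is.null(ont) && !is.null(ann)) {
    information_content(ont, ann)
  }

  class_pairs <- list(
    lncrna_mrna = c("lncRNA", "mRNA"),
    mrna_mirna = c("mRNA", "miRNA"),
    lncrna_mirna = c("lncRNA", "miRNA"))

  for (st in subtypes) {
    rec <- list(subtype = st, networks = list())
    mats <- lapply(split_m, function(per_st) {
      remove_outlier_samples(log2_shift_transform(per_st[[st]]),
                             k_sd = config$k_sd)
    })
    rec$features <- lapply(mats, function(m) nrow(m$values))
    rec$samples <- lapply(mats, function(m) ncol(m$values))

    nets <- list()
    for (pair in names(class_pairs)) {
      cls <- class_pairs[[pair]]
      zt <- pairwise_z_table(mats[[cls[1]]], mats[[cls[2]]], clip = TRUE)
      write_tsv(zt, file.path(config$out_dir,
                              sprintf("ztable_%s_%s.tsv", pair, st)))
      fit <- tryCatch(
        select_cutoff(zt, r2_min = config$r2_min,
                      slope_range = config$slope_range),
        no_cutoff = function(e) {
          note(sprintf("%s/%s: %s", st, pair, conditionMessage(e)))
          NULL
        })
      if (is.null(fit)) next
      net <- build_bipartite(zt, fit$cutoff, min_degree = config$min_degree)
      write_bipartite(net, file.path(config$out_dir,
                                     sprintf("network_%s_%s.tsv", pair, st)))
      nets[[pair]] <- net
      rec$networks[[pair]] <- list(
        cutoff = fit$cutoff, r_squared = fit$r_squared, slope = fit$slope,
        edges = nrow(net$edges), x_nodes = length(net$x_nodes),
        y_nodes = length(net$y_nodes))
    }

    coherent <- data.frame(node_a = character(0), node_b = character(0),
                           n_support = integer(0))
    if (!is.null(nets$lncrna_mrna) && !is.null(nets$lncrna_mirna) &&
        length(nets$lncrna_mrna$x_nodes) >= 2 &&
        length(nets$lncrna_mirna$x_nodes) >= 2) {
      recs <- similarity_records(
        pairwise_profile_similarity(nets$lncrna_mrna, "x"),
        pairwise_profile_similarity(nets$lncrna_mirna, "x"))
      recs <- assign_areas(recs, config$area_quantile)
      write_tsv(recs, file.path(config$out_dir,
                                sprintf("similarity_lncRNA_%s.tsv", st)))
      coherent <- select_coherent_pairs(
        recs, coherence_config(config$min_indices, config$top_frac,
                               config$area_quantile))
    } else {
      note(sprintf("%s: lncRNA similarity skipped (missing bipartite context)", st))
    }
    write_tsv(coherent, file.path(config$out_dir,
                                  sprintf("coherent_%s.tsv", st)))
    rec$coherent_pairs <- nrow(coherent)

    # mRNA-side similarities feed the area benchmark when a PPI list is given
    if (!is.null(ppi) && !is.null(nets$lncrna_mrna) &&
        !is.null(nets$mrna_mirna) &&
        length(nets$lncrna_mrna$y_nodes) >= 2 &&
        length(nets$mrna_mirna$x_nodes) >= 2) {
      mrecs <- assign_areas(similarity_records(
        pairwise_profile_similarity(nets$lncrna_mrna, "y"),
        pairwise_profile_similarity(nets$mrna_mirna, "x")),
        config$area_quantile)
      report <- area_functional_report(mrecs, ppi, stats_ns,
                                       score_min = config$ppi_score_min)
      write_tsv(report, file.path(config$out_dir,
                                  sprintf("area_report_%s.tsv", st)))
    }

    modules <- data.frame(node = character(0), module = integer(0))
    if (nrow(coherent) > 0) {
      g <- build_coherent_network(coherent)
      modules <- detect_modules(g, min_size = config$min_size,
                                seed = config$seed)
    }
    write_tsv(data.frame(node = modules$node,
                         subtype = rep(st, nrow(modules)),
                         module = modules$module),
              file.path(config$out_dir, sprintf("modules_%s.tsv", st)))
    rec$modules <- if (nrow(modules) > 0) {
      as.list(table(modules$module[modules$module > 0]))
    } else list()

    # per-module GO enrichment against the subtype's expressed mRNAs
    if (!is.null(ont) && !is.null(ann) && nrow(modules) > 0 &&
        !is.null(nets$lncrna_mrna)) {
      background <- features(mats$mRNA)
      for (k in sort(unique(modules$module[modules$module > 0]))) {
        lncs <- modules$node[modules$module == k]
        targets <- intersect(module_target_mrnas(lncs, nets$lncrna_mrna),
                             background)
        if (length(targets) == 0) next
        enr <- go_enrichment(targets, background, ann, ont,
                             namespace = "biological_process")
        write_tsv(enr, file.path(config$out_dir,
                                 sprintf("enrichment_%s_m%d.tsv", st, k)))
      }
    }
    manifest$subtypes[[st]] <- rec
  }

  files <- list.files(config$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest$checksums <- as.list(tools::md5sum(sort(files)))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
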