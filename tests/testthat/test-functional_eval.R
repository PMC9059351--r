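# a small two-namespace ontology used across these tests:
# BP: root -> b1 -> {t1, t2}, root -> t3 ; MF: root -> m1
tiny_ontology <- function() {
  terms <- data.frame(
    id = c("BP:0", "BP:1", "BP:2", "BP:3", "BP:4", "MF:0", "MF:1"),
    name = c("bp root", "branch", "term one", "term two", "term three",
             "mf root", "mf term"),
    namespace = c(rep("biological_process", 5), rep("molecular_function", 2)))
  parents <- list(`BP:0` = character(0), `BP:1` = "BP:0", `BP:2` = "BP:1",
                  `BP:3` = "BP:1", `BP:4` = "BP:0",
                  `MF:0` = character(0), `MF:1` = "MF:0")
  ontology(terms, parents)
}

tiny_annotations <- function() {
  data.frame(
    gene = c("g1", "g2", "g3", "g4", "g1", "g2"),
    term = c("BP:2", "BP:2", "BP:3", "BP:4", "MF:1", "MF:0"),
    namespace = c(rep("biological_process", 4), rep("molecular_function", 2)))
}

test_that("ppi_fraction counts unordered pairs above a strict score threshold", {
  ppi <- data.frame(gene_a = c("g1", "g3", "g5"),
                    gene_b = c("g2", "g4", "g6"),
                    score = c(0.99, 0.95, 0.96))
  pairs <- data.frame(node_a = c("g2", "g3", "g5"),
                      node_b = c("g1", "g4", "g6"))
  # g1-g2 matches (reversed order counts); g3-g4 sits exactly at 0.95
  # and is excluded by the strict rule; g5-g6 passes
  expect_equal(ppi_fraction(pairs, ppi, score_min = 0.95), 200 / 3)
  expect_equal(ppi_fraction(pairs[1, ], ppi), 100)
  expect_equal(ppi_fraction(pairs[2, ], ppi), 0)
  expect_error(ppi_fraction(pairs[0, ], ppi), "empty")
})

test_that("information content propagates annotations and is monotone", {
  st <- suppressMessages(information_content(tiny_ontology(), tiny_annotations()))
  bp <- st$biological_process
  expect_equal(bp$p[["BP:0"]], 1)
  expect_equal(bp$ic[["BP:0"]], 0)
  # BP:2 annotates g1, g2 of 4 annotated genes -> p = 1/2, IC = ln 2
  expect_equal(bp$p[["BP:2"]], 0.5)
  expect_equal(bp$ic[["BP:2"]], log(2), tolerance = 1e-12)
  # branch BP:1 inherits g1, g2, g3 -> p = 3/4
  expect_equal(bp$p[["BP:1"]], 0.75)
  # child -> parent monotonicity across every is_a edge
  ont <- tiny_ontology()
  for (id in names(bp$p)) {
    for (par in ont$parents[[id]]) {
      expect_gte(bp$p[[par]], bp$p[[id]])
    }
  }
})

test_that("sim_rel matches its closed form, is symmetric, and zeroes at the root", {
  st <- suppressMessages(information_content(tiny_ontology(), tiny_annotations()))
  bp <- st$biological_process
  # identical term: value reduces to 1 - p(c)
  expect_equal(sim_rel("BP:2", "BP:2", bp), 1 - bp$p[["BP:2"]])
  # terms whose only common ancestor is the root score 0
  expect_equal(sim_rel("BP:2", "BP:4", bp), 0)
  expect_equal(sim_rel("BP:0", "BP:0", bp), 0)
  # direct evaluation oracle for BP:2 vs BP:3 (MICA = BP:1)
  expected <- 2 * log(bp$p[["BP:1"]]) /
    (log(bp$p[["BP:2"]]) + log(bp$p[["BP:3"]])) * (1 - bp$p[["BP:1"]])
  expect_equal(sim_rel("BP:2", "BP:3", bp), expected, tolerance = 1e-12)
  # symmetry over all term pairs
  ids <- names(bp$p)
  for (a in ids) for (b in ids) {
    expect_equal(sim_rel(a, b, bp), sim_rel(b, a, bp), tolerance = 1e-12)
    expect_gte(sim_rel(a, b, bp), 0)
    expect_lt(sim_rel(a, b, bp), 1)
  }
})

test_that("funSim is bounded, zero for root-only genes, and group-separating", {
  st <- suppressMessages(information_content(tiny_ontology(), tiny_annotations()))
  # g4 is annotated to BP:4 whose MICA with anything else is the root
  expect_equal(funsim("g4", "g1", st), 0)
  expect_gt(funsim("g1", "g2", st), 0)
  expect_error(funsim("g1", "missing", st), "without annotations")

  co <- generate_cohort(small_config())
  toy <- generate_toy_ontology(co)
  stats <- suppressMessages(information_content(toy$ontology, toy$annotations))
  g <- co$truth$group_of$mrna
  members <- names(g)[g > 0]
  set.seed(51)
  same <- c(); cross <- c()
  for (i in 1:150) {
    pick <- sample(members, 2)
    fs <- funsim(pick[1], pick[2], stats)
    expect_gte(fs, 0); expect_lte(fs, 1)
    if (g[pick[1]] == g[pick[2]]) same <- c(same, fs) else cross <- c(cross, fs)
  }
  expect_gt(mean(same), mean(cross))
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # 10-gene background, one term annotating 5 genes
  bg <- paste0("g", 1:10)
  terms <- data.frame(id = c("BP:0", "BP:1"),
                      name = c("root", "term"),
                      namespace = "biological_process")
  ont <- ontology(terms, list(`BP:0` = character(0), `BP:1` = "BP:0"))
  ann <- data.frame(gene = bg,
                    term = c(rep("BP:1", 5), rep("BP:0", 5)),
                    namespace = "biological_process")
  out <- go_enrichment(bg[1:3], bg, ann, ont)
  expect_equal(out$p[out$term == "BP:1"], 10 / 120, tolerance = 1e-12)
  # the root annotates everything -> p = 1
  expect_equal(out$p[out$term == "BP:0"], 1)
  # exhaustive oracle over every gene set of size <= 4
  for (size in 1:4) {
    sets <- combn(10, size)
    for (j in seq_len(min(ncol(sets), 60))) {
      gs <- bg[sets[, j]]
      res <- go_enrichment(gs, bg, ann, ont)
      k <- sum(gs %in% bg[1:5])
      if (k == 0) {
        expect_equal(res$p[res$term == "BP:1"], 1, tolerance = 1e-12)
      } else {
        expect_equal(res$p[res$term == "BP:1"],
                     enum_hyper_p(k, 5, 10, size), tolerance = 1e-12)
      }
    }
  }
  # BH q-values are monotone in p and never smaller than p / correction
  expect_true(all(diff(out$p) >= 0))
  expect_equal(out$q, p.adjust(out$p, "BH"))
  expect_error(go_enrichment(character(0), bg, ann, ont), "empty")
  expect_error(go_enrichment("not_in_bg", bg, ann, ont), "subset")
})

test_that("module target mRNAs are neighborhood unions with a link threshold", {
  zt <- data.frame(
    feature_a = c("L1", "L1", "L2", "L2", "L3"), class_a = "lncRNA",
    feature_b = c("M1", "M2", "M2", "M3", "M4"), class_b = "mRNA",
    rs = 0.5, z = 5, n = 50)
  class(zt) <- c("z_table", "data.frame")
  net <- build_bipartite(zt, 1)
  expect_setequal(module_target_mrnas("L1", net), c("M1", "M2"))
  expect_setequal(module_target_mrnas(c("L1", "L2"), net),
                  c("M1", "M2", "M3"))
  # with min_links = 2 only the shared target survives
  expect_equal(module_target_mrnas(c("L1", "L2"), net, min_links = 2), "M2")
  expect_error(module_target_mrnas(character(0), net), "empty")
})

test_that("enrichment-profile clustering filters at strict q < 0.05 and cuts to k", {
  q <- rbind(
    mod1 = c(t1 = 1e-6, t2 = 0.5, t3 = 0.05, t4 = 0.8),
    mod2 = c(t1 = 1e-6, t2 = 0.5, t3 = 0.05, t4 = 0.8),
    mod3 = c(t1 = 0.9, t2 = 0.01, t3 = 0.05, t4 = 0.9))
  out <- cluster_enrichment_profiles(q, k = 2)
  # t3 sits exactly at 0.05 in its best module and is dropped; t4 never
  # passes
  expect_setequal(colnames(out$profile), c("t1", "t2"))
  # identical profiles merge first and share a cluster at k = 2
  expect_equal(out$clusters[["mod1"]], out$clusters[["mod2"]])
  expect_equal(length(unique(out$clusters)), 2)
  # cap applies to the -log10 transform
  expect_lte(max(out$profile), 10)
  expect_error(cluster_enrichment_profiles(q[1, , drop = FALSE]), "at least 2")
  expect_error(cluster_enrichment_profiles(matrix(0.9, 2, 2)), "no term")
})

test_that("OBO and annotation files round-trip", {
  ont <- tiny_ontology()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "toy.obo")
  write_obo(ont, path)
  back <- read_obo(path)
  expect_equal(back$terms, ont$terms)
  expect_equal(back$parents, ont$parents)
  expect_equal(back$roots, ont$roots)
  ann <- tiny_annotations()
  apath <- file.path(dir, "ann.tsv")
  write_annotations(ann, apath)
  expect_equal(read_annotations(apath), ann)
  # malformed ontologies are rejected
  expect_error(ontology(ont$terms[-1, ], ont$parents[-1]), "root|parent")
  cyc <- data.frame(id = c("X:0", "X:1", "X:2"), name = "x",
                    namespace = "biological_process")
  expect_error(
    ontology(cyc, list(`X:0` = character(0), `X:1` = "X:2", `X:2` = "X:1")),
    "cycle|root")
})
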