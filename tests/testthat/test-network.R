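toy_annotation <- function() {
  an <- make_annotation(c("tf1", "g1", "g2", "g3", "lnc1", "lnc2"),
                        biotype = c("coding", "coding", "coding", "coding",
                                    "lncRNA", "lncRNA"),
                        is_tf = c(TRUE, rep(FALSE, 5)))
  an
}

test_that("consistent DEMs require presence and agreement in all patients", {
  dem <- function(ids, dirs) data.frame(feature_id = ids, direction = dirs)
  tabs <- list(A = dem(c("m1", "m2", "m3"), c("up", "up", "up")),
               B = dem(c("m1", "m2"), c("up", "down")),
               C = dem(c("m1", "m2", "m4"), c("up", "up", "down")))
  res <- select_consistent_dems(tabs, c("A", "B", "C"))
  expect_equal(res$feature_id, "m1")        # m2 disagrees, m3/m4 missing
  expect_equal(res$direction, "up")
  expect_error(select_consistent_dems(tabs, character()), "empty")
  expect_error(select_consistent_dems(tabs, "Z"), "unknown")
})

test_that("miRNA-TF-gene assembly matches hand counts and constraints", {
  mirnas <- data.frame(feature_id = c("m1", "m2"),
                       direction = c("up", "down"))
  mt <- data.frame(regulator = c("m1", "m1", "m1", "m2", "m2", "m2"),
                   target = c("tf1", "g1", "g2", "g3", "lnc1", "lnc2"))
  tt <- data.frame(regulator = "tf1", target = "g1")
  degs <- c("tf1", "g1", "g2", "g3", "lnc1", "lnc2")
  mods <- data.frame(feature_id = degs,
                     module = c("blue", "blue", "turquoise", "turquoise",
                                "blue", "grey"))
  net <- assemble_mirna_tf_gene(mirnas, mt, tt, degs, mods,
                                annotation = toy_annotation())
  expect_equal(nrow(net$nodes), 8)          # 2 miRNA + 6 features
  expect_equal(sum(net$edges$kind == "mirna_target"), 6)
  expect_equal(sum(net$edges$kind == "tf_target"), 1)
  expect_equal(net$nodes$kind[net$nodes$id == "tf1"], "TF")
  expect_equal(net$nodes$kind[net$nodes$id == "lnc1"], "lncRNA")
  expect_equal(net$nodes$direction[net$nodes$id == "m2"], "down")

  # empty DEG union: only (isolated) miRNA nodes, with a warning
  expect_warning(
    net0 <- assemble_mirna_tf_gene(mirnas, mt, tt, character(), mods,
                                   annotation = toy_annotation()),
    "isolated")
  expect_equal(sort(net0$nodes$id), c("m1", "m2"))
  expect_equal(nrow(net0$edges), 0)

  # determinism: identical inputs give identical sorted tables
  net2 <- assemble_mirna_tf_gene(mirnas, mt, tt, degs, mods,
                                 annotation = toy_annotation())
  expect_identical(net, net2)
})

test_that("cross-module co-expression edges respect the |r| bound", {
  set.seed(61)
  prof <- rnorm(8)
  x <- rbind(g1 = prof, g2 = prof + rnorm(8, sd = 1e-3),
             g3 = rnorm(8), tf1 = rnorm(8))
  colnames(x) <- paste0("s", 1:8)
  mirnas <- data.frame(feature_id = "m1", direction = "up")
  mt <- data.frame(regulator = rep("m1", 4),
                   target = c("g1", "g2", "g3", "tf1"))
  mods <- data.frame(feature_id = c("g1", "g2", "g3", "tf1"),
                     module = c("blue", "turquoise", "brown", "blue"))
  net <- assemble_mirna_tf_gene(
    mirnas, mt, data.frame(regulator = character(), target = character()),
    c("g1", "g2", "g3", "tf1"), mods, expr = make_expr(x, "log2"),
    coexpr_r_min = 0.9, annotation = toy_annotation())
  ce <- net$edges[net$edges$kind == "coexpression", ]
  expect_equal(nrow(ce), 1)                  # only g1-g2 pass, diff modules
  expect_setequal(c(ce$source, ce$target), c("g1", "g2"))
  expect_gt(abs(ce$weight), 0.9)
})

test_that("within-module TF-gene-lncRNA assembly counts nodes and edges", {
  mods <- data.frame(
    feature_id = c("tf1", "g1", "g2", "g3", "lnc1", "lnc2", "g9"),
    module = c(rep("turquoise", 6), "blue"))
  pairs <- data.frame(feature_a = c("g1", "g2", "g9"),
                      feature_b = c("lnc1", "lnc2", "lnc1"),
                      r = c(0.95, 0.93, 0.99), p = c(1e-8, 1e-8, 1e-9))
  tt <- data.frame(regulator = "tf1", target = "g2")
  net <- assemble_tf_gene_lncrna("turquoise", mods, pairs, tt,
                                 annotation = toy_annotation())
  expect_equal(nrow(net$nodes), 6)
  expect_equal(sum(net$edges$kind == "coexpression"), 2)  # g9 pair excluded
  expect_equal(sum(net$edges$kind == "tf_target"), 1)
  expect_equal(sum(net$nodes$kind == "lncRNA"), 2)

  # enriched pathways only
  sets <- gene_set_collection(list(P1 = c("g1", "g2"), P2 = "g3"), "KEGG")
  enr <- data.frame(set = c("P1", "P2"), fdr = c(0.01, 0.8))
  net2 <- assemble_tf_gene_lncrna("turquoise", mods, pairs, tt,
                                  pathways = sets, enrichment = enr,
                                  annotation = toy_annotation())
  expect_equal(net2$nodes$id[net2$nodes$kind == "pathway"], "P1")
  expect_equal(sum(net2$edges$kind == "gene_pathway"), 2)

  no_enr <- assemble_tf_gene_lncrna("turquoise", mods, pairs, tt,
                                    pathways = sets,
                                    enrichment = enr[enr$fdr > 0.5, ],
                                    annotation = toy_annotation())
  expect_equal(sum(no_enr$nodes$kind == "pathway"), 0)
  expect_error(assemble_tf_gene_lncrna("red", mods, pairs, tt,
                                       annotation = toy_annotation()),
               "unknown module")
})

test_that("crosstalk nodes are ranked by pathway degree then id", {
  nodes <- data.frame(id = c("a", "b", "c", "d", "P1", "P2", "P3"),
                      kind = c(rep("gene", 3), "TF", rep("pathway", 3)))
  edges <- data.frame(
    source = c("a", "a", "a", "b", "b", "c", "c", "d"),
    target = c("P1", "P2", "P3", "P1", "P2", "P2", "P3", "P1"),
    kind = "gene_pathway")
  net <- regulatory_network(nodes, edges)
  expect_equal(find_crosstalk_nodes(net, 2), c("a", "b", "c"))
  expect_equal(find_crosstalk_nodes(net, 3), "a")
  single <- regulatory_network(nodes, edges[c(1, 4, 8), ])
  expect_equal(find_crosstalk_nodes(single, 2), character())
  expect_error(find_crosstalk_nodes(net, 1), ">= 2")
})

test_that("network validation enforces the type constraints", {
  nodes <- data.frame(id = c("m1", "g1", "P1"),
                      kind = c("miRNA", "gene", "pathway"))
  ok <- regulatory_network(nodes, data.frame(
    source = "m1", target = "g1", kind = "mirna_target"))
  expect_s3_class(ok, "regulatory_network")
  expect_error(regulatory_network(nodes, data.frame(
    source = "g1", target = "m1", kind = "mirna_target")), "miRNA")
  expect_error(regulatory_network(nodes, data.frame(
    source = "g1", target = "g1", kind = "tf_target")), "TF")
  expect_error(regulatory_network(nodes, data.frame(
    source = "g1", target = "m1", kind = "gene_pathway")), "pathway")
  expect_error(regulatory_network(nodes, data.frame(
    source = "m1", target = "zz", kind = "mirna_target")), "node")
  dup <- data.frame(source = c("m1", "m1"), target = c("g1", "g1"),
                    kind = "mirna_target")
  expect_error(regulatory_network(nodes, dup), "duplicate")
})

test_that("network export round-trips byte-stably in both formats", {
  nodes <- data.frame(id = c("m1", "tf1", "g1", "P1"),
                      kind = c("miRNA", "TF", "gene", "pathway"),
                      direction = c("up", NA, NA, NA),
                      module = c(NA, "blue", "blue", NA))
  edges <- data.frame(
    source = c("m1", "tf1", "g1"), target = c("g1", "g1", "P1"),
    kind = c("mirna_target", "tf_target", "gene_pathway"),
    weight = c(-0.87, NA, NA))
  net <- regulatory_network(nodes, edges)

  gpath <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gpath, "graphml")
  back <- import_network(gpath, "graphml")
  expect_equal(back, net)
  gpath2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(back, gpath2, "graphml")
  expect_identical(readLines(gpath), readLines(gpath2))

  # igraph parses the document and sees the same structure
  ig <- igraph::read_graph(gpath, format = "graphml")
  expect_equal(igraph::vcount(ig), 4)
  expect_equal(igraph::ecount(ig), 3)
  expect_setequal(igraph::vertex_attr(ig, "kind"),
                  c("miRNA", "TF", "gene", "pathway"))

  tprefix <- file.path(withr::local_tempdir(), "net")
  export_network(net, tprefix, "tsv")
  expect_equal(import_network(tprefix, "tsv"), net)

  empty <- regulatory_network(data.frame(id = character(),
                                         kind = character()))
  epath <- withr::local_tempfile(fileext = ".graphml")
  export_network(empty, epath, "graphml")
  expect_equal(nrow(import_network(epath, "graphml")$nodes), 0)

  counts_in_file <- sum(grepl("<node ", readLines(gpath)))
  expect_equal(counts_in_file, nrow(net$nodes))
})

test_that("assembled planted networks are sound and complete", {
  coh <- generate_cohort(small_scenario(seed = 9))
  edges <- generate_edge_tables(coh$truth$config, coh$truth,
                                decoy_fraction = 0.3)
  fp <- fpkm(coh$counts, coh$annotation)
  mt <- tpm(coh$mirna_counts, coh$mirna_annotation)
  meta <- coh$metadata
  deg_tables <- run_default_de(coh)
  dem_tables <- lapply(stats::setNames(nm = unique(meta$patient)),
                       function(p)
    call_features(mt[, paste0(p, "_D0"), drop = FALSE],
                  mt[, paste0(p, "_D14"), drop = FALSE], patient = p))
  remissive <- unique(meta$patient[meta$remission == "R"])
  important <- select_consistent_dems(dem_tables, remissive)
  deg_union <- unique(unlist(lapply(deg_tables, `[[`, "feature_id")))
  mods <- data.frame(feature_id = names(coh$truth$module_of),
                     module = unname(coh$truth$module_of))
  net <- suppressWarnings(assemble_mirna_tf_gene(
    important, edges$mirna_targets, edges$tf_targets, deg_union, mods,
    annotation = coh$annotation))
  # soundness: every regulatory edge exists in the input tables
  me <- net$edges[net$edges$kind == "mirna_target", ]
  expect_true(all(paste(me$source, me$target) %in%
                    paste(edges$mirna_targets$regulator,
                          edges$mirna_targets$target)))
  # completeness: every planted edge whose miRNA is consistent and whose
  # target was called differential appears
  planted <- coh$truth$mirna_target_edges
  qualifying <- planted[planted$regulator %in% important$feature_id &
                          planted$target %in% deg_union, ]
  expect_gt(nrow(qualifying), 0)
  expect_true(all(paste(qualifying$regulator, qualifying$target) %in%
                    paste(me$source, me$target)))
})
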