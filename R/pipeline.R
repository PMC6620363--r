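ALL_STAGES <- c("simulate", "quantify", "de", "coexpress", "enrich",
                "immune", "network")

default_pipeline_config <- function() {
  list(seed = 1L, outdir = "cartx_out",
       inputs = NULL,
       simulate = list(decoy_fraction = 0.2, gmt_overlap = 0.8,
                       n_random_sets = 3L),
       quantify = list(gene_threshold = 1, mirna_threshold = 10,
                       min_samples = 1L, high_threshold = 100,
                       top_k = 10L),
       de = list(min_lfc = 1, pseudocount = 0.1),
       coexpress = list(power = 6, auto_power = FALSE,
                        min_module_size = 30L, cut_height = 0.99,
                        pair_r_min = 0.9, pair_p_max = 1e-6,
                        n_top_pairs = 200L),
       enrich = list(top_kegg = 20L, top_bp = 15L),
       immune = list(r_min = 0.5, p_max = 0.05, fc_threshold = 2),
       network = list(coexpr_r_min = 0.9, min_pathways = 2L))
}

merge_config <- function(base, user) {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) stop("unknown config key: ", unknown[1])
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read a pipeline configuration file
#'
#' YAML file with top-level keys `seed`, `outdir`, and optional per-stage
#' blocks (`simulate`, `quantify`, `de`, `coexpress`, `enrich`, `immune`,
#' `network`) or an `inputs` block of file paths. Unknown keys are
#' rejected. A run uses either the `inputs` block or simulation, never
#' both.
#'
#' @param path YAML file.
#' @return Resolved configuration list with all defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_pipeline_config()
  # the simulate block may carry scenario overrides unknown to the defaults
  sim_extra <- setdiff(names(user$simulate),
                       c(names(base$simulate),
                         names(formals(scenario_config))))
  if (length(sim_extra)) stop("unknown simulate key: ", sim_extra[1])
  if (!is.null(user$simulate)) {
    extra <- user$simulate[setdiff(names(user$simulate),
                                   names(base$simulate))]
    user$simulate <- user$simulate[intersect(names(user$simulate),
                                             names(base$simulate))]
    cfg <- merge_config(base, user)
    cfg$simulate <- c(cfg$simulate, extra)
    cfg
  } else {
    merge_config(base, user)
  }
}

stage_seed <- function(cfg, stage) {
  as.integer(cfg$seed) + match(stage, ALL_STAGES)
}

record <- function(manifest, stage, files) {
  rbind(manifest, data.frame(stage = stage, file = basename(files),
                             md5 = unname(tools::md5sum(files)),
                             stringsAsFactors = FALSE))
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in their canonical order
#' (`simulate`, `quantify`, `de`, `coexpress`, `enrich`, `immune`,
#' `network`), writing every intermediate table as flat text under
#' `outdir`, recording the fully resolved parameter set
#' (`params_used.yaml`), and emitting a manifest of produced files with md5
#' checksums (`manifest.tsv`). Reruns with identical configuration and seed
#' reproduce identical checksums.
#'
#' @param config Configuration list (see [read_pipeline_config()]) or a
#'   YAML file path. When no `inputs` block is given, the cohort is
#'   simulated from the `simulate` block (defaults: [default_scenario()]).
#' @param stages Ordered subset of the stage names (default: all).
#' @return Manifest `data.frame` (`stage`, `file`, `md5`), invisibly; the
#'   full in-memory state is attached as attribute `state`.
#' @export
run_pipeline <- function(config = list(), stages = ALL_STAGES) {
  if (is.character(config)) config <- read_pipeline_config(config)
  else {
    base <- default_pipeline_config()
    extra <- config$simulate[setdiff(names(config$simulate),
                                     names(base$simulate))]
    if (!is.null(config$simulate))
      config$simulate <- config$simulate[
        intersect(names(config$simulate), names(base$simulate))]
    config <- merge_config(base, config)
    config$simulate <- c(config$simulate, extra)
  }
  bad <- setdiff(stages, ALL_STAGES)
  if (length(bad)) stop("unknown stage: ", bad[1])
  stages <- ALL_STAGES[ALL_STAGES %in% stages]
  if (!is.null(config$inputs) && "simulate" %in% stages)
    stop("a run uses either the inputs block or the simulate stage")
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  manifest <- data.frame(stage = character(), file = character(),
                         md5 = character(), stringsAsFactors = FALSE)
  st <- list(config = config)

  if (!is.null(config$inputs)) st <- load_inputs(st, config$inputs)

  for (stage in stages) {
    need <- switch(stage,
                   quantify = "counts", de = "gene_fpkm",
                   coexpress = "gene_fpkm", enrich = "deg_tables",
                   immune = "gene_fpkm", network = "dem_tables", NULL)
    if (!is.null(need) && is.null(st[[need]]))
      stop("stage `", stage, "` requires missing upstream output `",
           need, "`")
    set.seed(stage_seed(config, stage))
    st <- switch(stage,
                 simulate = stage_simulate(st, outdir),
                 quantify = stage_quantify(st, outdir),
                 de = stage_de(st, outdir),
                 coexpress = stage_coexpress(st, outdir),
                 enrich = stage_enrich(st, outdir),
                 immune = stage_immune(st, outdir),
                 network = stage_network(st, outdir))
    manifest <- record(manifest, stage, st$new_files)
  }
  yaml::write_yaml(config, file.path(outdir, "params_used.yaml"))
  data.table::fwrite(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t")
  attr(manifest, "state") <- st
  invisible(manifest)
}

load_inputs <- function(st, inputs) {
  need <- c("counts", "mirna_counts", "annotation", "mirna_annotation",
            "metadata", "mirna_targets", "tf_targets", "gmt", "panel")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) stop("inputs block lacks: ", miss[1])
  st$counts <- read_expr_matrix(inputs$counts)
  st$mirna_counts <- read_expr_matrix(inputs$mirna_counts)
  st$annotation <- read_annotation(inputs$annotation)
  st$mirna_annotation <- read_annotation(inputs$mirna_annotation)
  st$metadata <- as.data.frame(data.table::fread(inputs$metadata))
  st$mirna_targets <- as.data.frame(data.table::fread(inputs$mirna_targets))
  st$tf_targets <- as.data.frame(data.table::fread(inputs$tf_targets))
  st$gene_sets <- read_gmt(inputs$gmt)
  st$panel <- read_marker_panel(inputs$panel)
  st
}

stage_simulate <- function(st, outdir) {
  sim <- st$config$simulate
  scen_args <- sim[intersect(names(sim), names(formals(scenario_config)))]
  if (is.null(scen_args$seed)) scen_args$seed <- st$config$seed
  scenario <- if (length(setdiff(names(scen_args), "seed")) == 0L)
    do.call(default_scenario, scen_args)
  else do.call(scenario_config, scen_args)
  cohort <- generate_cohort(scenario)
  dir <- file.path(outdir, "simulate")
  write_cohort(cohort, dir)
  edges <- generate_edge_tables(scenario, cohort$truth,
                                decoy_fraction = sim$decoy_fraction,
                                dir = dir)
  sets <- generate_gene_sets(scenario, cohort$truth,
                             overlap = sim$gmt_overlap,
                             n_random = sim$n_random_sets,
                             path = file.path(dir, "gene_sets.gmt"))
  st$scenario <- scenario
  st$cohort <- cohort
  st$counts <- cohort$counts
  st$mirna_counts <- cohort$mirna_counts
  st$annotation <- cohort$annotation
  st$mirna_annotation <- cohort$mirna_annotation
  st$metadata <- cohort$metadata
  st$mirna_targets <- edges$mirna_targets
  st$tf_targets <- edges$tf_targets
  st$gene_sets <- sets
  st$panel <- cohort$truth$marker_panel
  st$new_files <- list.files(dir, full.names = TRUE)
  st
}

stage_quantify <- function(st, outdir) {
  q <- st$config$quantify
  st$gene_fpkm_all <- fpkm(st$counts, st$annotation)
  st$gene_tpm_all <- tpm(st$counts, st$annotation)
  st$mirna_tpm_all <- tpm(st$mirna_counts, st$mirna_annotation)
  st$gene_fpkm <- filter_expressed(st$gene_fpkm_all, q$gene_threshold,
                                   q$min_samples)
  st$mirna_tpm <- filter_expressed(st$mirna_tpm_all, q$mirna_threshold,
                                   q$min_samples)
  st$high_genes <- highly_expressed(st$gene_fpkm, q$high_threshold)
  st$mirna_share <- top_abundance_share(st$mirna_tpm, q$top_k)
  files <- file.path(outdir, c("gene_fpkm.tsv", "gene_tpm.tsv",
                               "mirna_tpm.tsv", "highly_expressed.tsv",
                               "mirna_top_share.tsv"))
  write_expr_matrix(st$gene_fpkm, files[1])
  write_expr_matrix(st$gene_tpm_all, files[2])
  write_expr_matrix(st$mirna_tpm, files[3])
  data.table::fwrite(data.frame(feature_id = st$high_genes), files[4],
                     sep = "\t")
  data.table::fwrite(data.frame(sample_id = names(st$mirna_share$share),
                                share = unname(st$mirna_share$share)),
                     files[5], sep = "\t")
  st$new_files <- files
  st
}

paired_tables <- function(expr, metadata, min_lfc, pseudocount) {
  tables <- list()
  for (p in unique(metadata$patient)) {
    pre_id <- metadata$sample_id[metadata$patient == p &
                                   metadata$timepoint == "D0"]
    post_id <- metadata$sample_id[metadata$patient == p &
                                    metadata$timepoint == "D14"]
    tables[[p]] <- call_features(expr[, pre_id, drop = FALSE],
                                 expr[, post_id, drop = FALSE],
                                 min_abs_log2fc = min_lfc,
                                 pseudocount = pseudocount, patient = p)
  }
  tables
}

stage_de <- function(st, outdir) {
  d <- st$config$de
  st$deg_tables <- paired_tables(st$gene_fpkm, st$metadata, d$min_lfc,
                                 d$pseudocount)
  st$dem_tables <- paired_tables(st$mirna_tpm, st$metadata, d$min_lfc,
                                 d$pseudocount)
  st$deg_union <- sort(unique(unlist(lapply(st$deg_tables, `[[`,
                                            "feature_id"))))
  remissive <- unique(st$metadata$patient[st$metadata$remission == "R"])
  st$remissive <- remissive
  inter <- intersect_common(st$deg_tables, remissive)
  files <- file.path(outdir, c("deg_tables.tsv", "dem_tables.tsv",
                               "deg_common.tsv"))
  data.table::fwrite(do.call(rbind, st$deg_tables), files[1], sep = "\t")
  data.table::fwrite(do.call(rbind, st$dem_tables), files[2], sep = "\t")
  data.table::fwrite(
    data.frame(feature_id = inter$common,
               same_trend = inter$common %in% inter$same_trend),
    files[3], sep = "\t")
  st$deg_common <- inter
  st$new_files <- files
  st
}

stage_coexpress <- function(st, outdir) {
  cx <- st$config$coexpress
  m <- unclass(st$gene_fpkm)
  lg <- log2(m + 1)
  lg <- lg[apply(lg, 1L, stats::sd) > 0, , drop = FALSE]
  expr <- expr_matrix(lg, "log2")
  power <- cx$power
  diag_file <- NULL
  if (isTRUE(cx$auto_power)) {
    sel <- pick_soft_power(expr)
    power <- sel$power
    diag_file <- file.path(outdir, "soft_power.tsv")
    data.table::fwrite(sel$diagnostics, diag_file, sep = "\t")
  }
  tom <- topological_overlap(adjacency(expr, power))
  st$modules <- detect_modules(tom, cx$min_module_size, cx$cut_height)
  st$eigengenes <- module_eigengene(expr, st$modules)
  st$log_expr <- expr
  activity <- pathway_activity(expr, st$gene_sets)
  st$module_pathway <- module_feature_correlation(st$eigengenes, activity)
  coding <- st$annotation$feature_id[st$annotation$biotype == "coding"]
  lnc <- st$annotation$feature_id[st$annotation$biotype == "lncRNA"]
  st$gene_lnc_pairs <- top_corr_pairs(intersect(coding, rownames(expr)),
                                      intersect(lnc, rownames(expr)),
                                      expr, cx$n_top_pairs,
                                      cx$pair_r_min, cx$pair_p_max)
  files <- file.path(outdir, c("modules.tsv", "eigengenes.tsv",
                               "module_pathway_correlation.tsv",
                               "gene_lncrna_pairs.tsv"))
  data.table::fwrite(st$modules, files[1], sep = "\t")
  data.table::fwrite(data.frame(module = rownames(st$eigengenes),
                                st$eigengenes, check.names = FALSE),
                     files[2], sep = "\t")
  data.table::fwrite(st$module_pathway, files[3], sep = "\t")
  data.table::fwrite(st$gene_lnc_pairs, files[4], sep = "\t")
  st$new_files <- c(files, diag_file)
  st
}

stage_enrich <- function(st, outdir) {
  en <- st$config$enrich
  background <- rownames(st$gene_fpkm)
  query <- intersect(st$deg_union, background)
  st$deg_enrichment <- fisher_enrich(query, background, st$gene_sets)
  st$deg_top_terms <- top_terms(st$deg_enrichment, en$top_kegg, en$top_bp)
  histones <- intersect(
    st$annotation$feature_id[st$annotation$is_histone],
    st$modules$feature_id)
  st$histone_chisq <- if (length(histones))
    class_chisq(st$modules, histones) else NULL
  files <- file.path(outdir, c("deg_enrichment.tsv", "deg_top_terms.tsv",
                               "histone_chisq.tsv"))
  data.table::fwrite(st$deg_enrichment, files[1], sep = "\t")
  data.table::fwrite(st$deg_top_terms, files[2], sep = "\t")
  hx <- st$histone_chisq
  data.table::fwrite(
    data.frame(statistic = if (is.null(hx)) NA else hx$statistic,
               p = if (is.null(hx)) NA else hx$p),
    files[3], sep = "\t")
  st$new_files <- files
  st
}

stage_immune <- function(st, outdir) {
  im <- st$config$immune
  st$cell_scores <- cell_scores(st$gene_fpkm_all, st$panel)
  st$proportions <- scores_to_proportions(st$cell_scores)
  anchors <- intersect(c("CAR", "CD19"), rownames(st$gene_fpkm_all))
  candidates <- st$annotation$feature_id[st$annotation$is_membrane]
  st$anchor_corr <- if (length(anchors))
    anchor_correlation(st$gene_fpkm_all, anchors, candidates,
                       im$r_min, im$p_max) else NULL
  pairs <- data.frame(
    patient = unique(st$metadata$patient),
    pre = st$metadata$sample_id[st$metadata$timepoint == "D0"],
    post = st$metadata$sample_id[st$metadata$timepoint == "D14"],
    stringsAsFactors = FALSE)
  st$panel_fc <- panel_foldchange_report(st$gene_fpkm_all, st$panel,
                                         pairs, im$fc_threshold)
  files <- file.path(outdir, c("cell_scores.tsv", "cell_proportions.tsv",
                               "anchor_correlation.tsv",
                               "panel_foldchange.tsv"))
  data.table::fwrite(data.frame(sample_id = rownames(st$cell_scores),
                                st$cell_scores, check.names = FALSE),
                     files[1], sep = "\t")
  data.table::fwrite(data.frame(sample_id = rownames(st$proportions),
                                st$proportions, check.names = FALSE),
                     files[2], sep = "\t")
  if (!is.null(st$anchor_corr) && nrow(st$anchor_corr))
    data.table::fwrite(st$anchor_corr, files[3], sep = "\t")
  else writeLines("feature_id", files[3])
  data.table::fwrite(st$panel_fc, files[4], sep = "\t")
  st$new_files <- files
  st
}

stage_network <- function(st, outdir) {
  nw <- st$config$network
  st$important_mirnas <- select_consistent_dems(st$dem_tables,
                                                st$remissive)
  st$network <- assemble_mirna_tf_gene(
    st$important_mirnas, st$mirna_targets, st$tf_targets, st$deg_union,
    st$modules, st$gene_sets, st$log_expr, st$mirna_tpm,
    nw$coexpr_r_min, st$annotation)
  st$crosstalk <- find_crosstalk_nodes(st$network, nw$min_pathways)
  files <- c(file.path(outdir, "network.graphml"),
             paste0(file.path(outdir, "network"),
                    c("_nodes.tsv", "_edges.tsv")),
             file.path(outdir, "crosstalk_nodes.tsv"))
  export_network(st$network, files[1], "graphml")
  export_network(st$network, file.path(outdir, "network"), "tsv")
  data.table::fwrite(data.frame(feature_id = st$crosstalk), files[4],
                     sep = "\t")
  st$new_files <- files
  st
}
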