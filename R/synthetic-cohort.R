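#' Scenario configuration for the synthetic paired cohort
#'
#' Describes a paired pre-/post-therapy bulk bone-marrow cohort with planted
#' structure: co-expression modules driven by patient-level eigengene factors,
#' treatment fold-changes at the post timepoint, miRNA-mediated repression of
#' target genes, cell-type mixtures observed through marker genes, and a CAR
#' transgene feature that appears after infusion in remissive patients.
#'
#' Gene expression is built on the log2 scale as
#' `x = base + loading * eigengene(patient) + shift * I(post) +
#'  repression + noise`, exponentiated, scaled so the average sample depth
#' equals `library_size`, and rounded to integer counts. Eigengene factors
#' are drawn per patient (shared by the patient's two timepoints), so paired
#' within-patient contrasts isolate the planted treatment shifts while
#' cross-sample correlation still carries the module structure.
#'
#' @param n_patients Number of patients (>= 2).
#' @param remission Named character vector, one of `"R"`/`"NR"` per patient;
#'   names are patient identifiers.
#' @param n_coding,n_lncrna,n_mirna Feature counts per biotype (the CAR and
#'   CD19 rows are added on top of `n_coding`).
#' @param n_tf,n_histone,n_membrane Number of coding genes flagged as
#'   transcription factors, histones and membrane proteins.
#' @param n_modules,module_sizes Planted co-expression modules; sizes must
#'   sum to at most `n_coding + n_lncrna` minus markers.
#' @param eigengene_sd SD of the per-patient module factors (log2 units).
#' @param loading_range Interval for per-gene positive factor loadings.
#' @param noise_sd SD of i.i.d. Gaussian noise on the log2 scale.
#' @param de_fraction Fraction of (non-marker) features receiving a
#'   treatment shift; also applied to miRNAs.
#' @param de_log2fc Magnitude of the post-vs-pre shift in log2 units.
#' @param mirna_repression_strength Non-positive coupling of each planted
#'   target to its regulator's centred log2 abundance.
#' @param targets_per_mirna Planted targets per differential miRNA.
#' @param cell_types `data.frame` with columns `name` and `n_markers`.
#' @param proportions Optional samples x cell-types matrix of true mixing
#'   proportions (rows sum to 1, sample order: patients in order, D0 then
#'   D14). `NULL` draws per-sample proportions from a symmetric Dirichlet.
#' @param gene_length_range Interval (bp) for simulated feature lengths.
#' @param library_size Average per-sample sequencing depth (counts).
#' @param seed Integer seed; identical configurations with identical seeds
#'   reproduce byte-identical outputs.
#' @return A validated `scenario_config` list.
#' @seealso [default_scenario()], [generate_cohort()]
#' @export
scenario_config <- function(n_patients = 4L,
                            remission = NULL,
                            n_coding = 520L, n_lncrna = 80L, n_mirna = 60L,
                            n_tf = 30L, n_histone = 20L, n_membrane = 40L,
                            n_modules = 5L, module_sizes = rep(100L, 5L),
                            eigengene_sd = 0.22, loading_range = c(0.7, 1),
                            antiphase_fraction = 0.5,
                            noise_sd = 0.1,
                            de_fraction = 0.1, de_log2fc = 2,
                            mirna_repression_strength = -0.8,
                            targets_per_mirna = 3L,
                            cell_types = data.frame(
                              name = c("B_cell", "CD8_T", "NK", "Monocyte"),
                              n_markers = 6L),
                            proportions = NULL,
                            gene_length_range = c(500L, 5000L),
                            library_size = 2e6,
                            seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), remission = remission,
              n_coding = as.integer(n_coding),
              n_lncrna = as.integer(n_lncrna),
              n_mirna = as.integer(n_mirna),
              n_tf = as.integer(n_tf), n_histone = as.integer(n_histone),
              n_membrane = as.integer(n_membrane),
              n_modules = as.integer(n_modules),
              module_sizes = as.integer(module_sizes),
              eigengene_sd = eigengene_sd, loading_range = loading_range,
              antiphase_fraction = antiphase_fraction,
              noise_sd = noise_sd, de_fraction = de_fraction,
              de_log2fc = de_log2fc,
              mirna_repression_strength = mirna_repression_strength,
              targets_per_mirna = as.integer(targets_per_mirna),
              cell_types = cell_types, proportions = proportions,
              gene_length_range = gene_length_range,
              library_size = library_size, seed = as.integer(seed))
  if (is.null(cfg$remission)) {
    lab <- rep("R", cfg$n_patients)
    if (cfg$n_patients >= 2) lab[2] <- "NR"
    names(lab) <- default_patient_ids(lab)
    cfg$remission <- lab
  }
  validate_scenario(cfg)
  class(cfg) <- "scenario_config"
  cfg
}

default_patient_ids <- function(labels) {
  paste0(labels, "-", LETTERS[seq_along(labels)])
}

validate_scenario <- function(cfg) {
  if (cfg$n_patients < 2L) stop("need at least 2 patients")
  if (length(cfg$remission) != cfg$n_patients ||
      !all(cfg$remission %in% c("R", "NR")))
    stop("remission must label every patient as R or NR")
  if (is.null(names(cfg$remission)) || anyDuplicated(names(cfg$remission)))
    stop("remission must carry unique patient names")
  if (length(cfg$module_sizes) != cfg$n_modules)
    stop("module_sizes must have length n_modules")
  n_markers <- sum(cfg$cell_types$n_markers)
  if (sum(cfg$module_sizes) > cfg$n_coding + cfg$n_lncrna - n_markers)
    stop("module sizes exceed the available gene count")
  if (any(cfg$module_sizes < 2L)) stop("module sizes must be >= 2")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stop("de_fraction must be in [0, 1]")
  if (cfg$noise_sd < 0 || cfg$eigengene_sd <= 0)
    stop("noise_sd must be >= 0 and eigengene_sd > 0")
  if (cfg$mirna_repression_strength > 0)
    stop("mirna_repression_strength must be <= 0")
  n_contrasts <- if (length(unique(cfg$remission)) > 1L) 3L else 2L
  if (cfg$n_modules > 2L * cfg$n_patients - n_contrasts)
    stop("cannot plant more orthogonal modules than residual sample ",
         "degrees of freedom after the treatment contrasts")
  if (cfg$library_size <= 0) stop("library_size must be positive")
  if (any(cfg$loading_range <= 0) || diff(cfg$loading_range) < 0)
    stop("loading_range must be a positive non-decreasing interval")
  if (cfg$antiphase_fraction < 0 || cfg$antiphase_fraction > 1)
    stop("antiphase_fraction must be in [0, 1]")
  if (cfg$n_tf + cfg$n_histone > cfg$n_coding)
    stop("more flagged genes than coding genes")
  if (!is.null(cfg$proportions)) {
    P <- cfg$proportions
    if (ncol(P) != nrow(cfg$cell_types) ||
        nrow(P) != 2L * cfg$n_patients)
      stop("proportions must be (2 * n_patients) x n_cell_types")
    if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9))
      stop("per-sample proportions must be non-negative and sum to 1")
  }
  invisible(cfg)
}

#' Default synthetic scenario
#'
#' Mirrors the study shape this package targets: 4 patients (3 remissive,
#' 1 non-remissive), two timepoints (D0, D14), 5 planted modules of 100
#' genes across ~600 coding/lncRNA features, 60 miRNAs, and a 4-population
#' immune mixture whose composition shifts after therapy in remissive
#' patients (B-cell depletion, CD8/NK expansion).
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
default_scenario <- function(seed = 1L, ...) {
  remission <- c("R-A" = "R", "NR-B" = "NR", "R-C" = "R", "R-D" = "R")
  d0 <- c(0.55, 0.12, 0.08, 0.25)
  d14_r <- c(0.08, 0.40, 0.28, 0.24)
  d14_nr <- c(0.50, 0.14, 0.09, 0.27)
  P <- rbind(d0, d14_r, d0, d14_nr, d0, d14_r, d0, d14_r)
  colnames(P) <- c("B_cell", "CD8_T", "NK", "Monocyte")
  rownames(P) <- NULL
  args <- list(n_patients = 4L, remission = remission,
               proportions = P, seed = seed)
  user <- list(...)
  args[names(user)] <- user
  do.call(scenario_config, args)
}

sample_table <- function(cfg) {
  patients <- names(cfg$remission)
  data.frame(
    sample_id = paste(rep(patients, each = 2L), c("D0", "D14"), sep = "_"),
    patient = rep(patients, each = 2L),
    timepoint = rep(c("D0", "D14"), cfg$n_patients),
    remission = rep(unname(cfg$remission), each = 2L),
    stringsAsFactors = FALSE)
}

#' Generate a paired synthetic cohort with ground truth
#'
#' Draws the full cohort described by a [scenario_config()]: a gene-level
#' count matrix (coding + lncRNA + CAR + CD19 rows), a miRNA count matrix,
#' a feature annotation table, sample metadata, and a `truth` list recording
#' every planted signal (module memberships, differential directions,
#' regulator-target edges, mixing proportions, marker panel) for downstream
#' recovery scoring.
#'
#' @param config A `scenario_config`.
#' @return List with elements `counts`, `mirna_counts` (both
#'   [expr_matrix] in `raw_count` unit), `annotation`, `metadata`, `truth`.
#' @export
generate_cohort <- function(config) {
  cfg <- validate_scenario(config)
  set.seed(cfg$seed)
  meta <- sample_table(cfg)
  n_s <- nrow(meta)
  is_post <- meta$timepoint == "D14"

  gene_ids <- sprintf("gene%04d", seq_len(cfg$n_coding))
  lnc_ids <- sprintf("lnc%04d", seq_len(cfg$n_lncrna))
  mir_ids <- sprintf("mir%03d", seq_len(cfg$n_mirna))

  # cell-type markers come from the coding pool and stay out of modules/DE
  ct <- cfg$cell_types
  marker_ids <- sample(gene_ids, sum(ct$n_markers))
  marker_of <- rep(ct$name, ct$n_markers)
  names(marker_of) <- marker_ids

  P <- cfg$proportions
  if (is.null(P)) {
    P <- matrix(stats::rgamma(n_s * nrow(ct), shape = 5), n_s)
    P <- P / rowSums(P)
    colnames(P) <- ct$name
  }
  rownames(P) <- meta$sample_id

  # planted modules over the non-marker coding + lncRNA pool
  pool <- c(setdiff(gene_ids, marker_ids), lnc_ids)
  module_members <- vector("list", cfg$n_modules)
  remaining <- pool
  for (m in seq_len(cfg$n_modules)) {
    module_members[[m]] <- sample(remaining, cfg$module_sizes[m])
    remaining <- setdiff(remaining, module_members[[m]])
  }
  all_gene_ids <- c(gene_ids, lnc_ids, "CAR", "CD19")
  module_of <- stats::setNames(rep("grey", length(all_gene_ids)),
                               all_gene_ids)
  for (m in seq_len(cfg$n_modules))
    module_of[module_members[[m]]] <- sprintf("planted%d", m)

  # functional flags; histones concentrate in modules, mirroring the kind of
  # class enrichment the chi-square screen is meant to detect
  nonmarker_coding <- setdiff(gene_ids, marker_ids)
  tf_ids <- sample(nonmarker_coding, cfg$n_tf)
  module_coding <- intersect(unlist(module_members), gene_ids)
  hist_pool <- if (length(module_coding) >= cfg$n_histone) module_coding
               else nonmarker_coding
  histone_ids <- sample(hist_pool, cfg$n_histone)
  membrane_ids <- unique(c("CD19",
    sample(c(marker_ids, setdiff(nonmarker_coding, unlist(module_members))),
           max(cfg$n_membrane - 1L, 0L))))

  # treatment shifts are planted outside modules so the two planted signal
  # layers (correlation structure, paired contrasts) stay identifiable
  de_eligible <- remaining
  n_de <- round(cfg$de_fraction * length(de_eligible))
  de_ids <- sort(sample(de_eligible, n_de))
  shift <- stats::setNames(rep(0, length(all_gene_ids)), all_gene_ids)
  shift[de_ids] <- sample(c(1, -1), n_de, replace = TRUE) * cfg$de_log2fc

  # miRNAs: skewed abundance (a let-7-like handful dominates), some shifted
  mir_base <- stats::rnorm(cfg$n_mirna, 8, 1.5)
  n_top <- min(7L, cfg$n_mirna)
  mir_base[seq_len(n_top)] <- mir_base[seq_len(n_top)] + 5
  n_dem <- max(2L, round(cfg$de_fraction * cfg$n_mirna))
  dem_ids <- sort(sample(mir_ids, n_dem))
  mir_shift <- stats::setNames(rep(0, cfg$n_mirna), mir_ids)
  mir_shift[dem_ids] <- sample(c(1, -1), n_dem, replace = TRUE) *
    cfg$de_log2fc
  mir_log <- matrix(mir_base, cfg$n_mirna, n_s) +
    outer(mir_shift, as.numeric(is_post)) +
    matrix(stats::rnorm(cfg$n_mirna * n_s, 0, cfg$noise_sd), cfg$n_mirna)
  dimnames(mir_log) <- list(mir_ids, meta$sample_id)

  # planted repression: each shifted miRNA couples to unmodelled grey genes
  target_pool <- setdiff(nonmarker_coding,
                         c(unlist(module_members), de_ids))
  n_targets <- min(length(dem_ids) * cfg$targets_per_mirna,
                   length(target_pool))
  target_draw <- sample(target_pool, n_targets)
  mirna_edges <- data.frame(
    regulator = rep(dem_ids, each = cfg$targets_per_mirna)[
      seq_len(n_targets)],
    target = target_draw, stringsAsFactors = FALSE)
  mirna_edges <- mirna_edges[order(mirna_edges$regulator,
                                   mirna_edges$target), , drop = FALSE]
  rownames(mirna_edges) <- NULL

  # TF->target edges inside modules (co-regulated by construction)
  tf_edges_list <- list()
  for (m in seq_len(cfg$n_modules)) {
    tfs_m <- intersect(tf_ids, module_members[[m]])
    cands <- setdiff(intersect(module_members[[m]], gene_ids), tf_ids)
    for (tf in tfs_m) {
      k <- min(3L, length(cands))
      if (k > 0)
        tf_edges_list[[length(tf_edges_list) + 1L]] <-
          data.frame(regulator = tf, target = sample(cands, k),
                     stringsAsFactors = FALSE)
    }
  }
  tf_edges <- if (length(tf_edges_list))
    do.call(rbind, tf_edges_list)
  else data.frame(regulator = character(), target = character(),
                  stringsAsFactors = FALSE)
  tf_edges <- tf_edges[order(tf_edges$regulator, tf_edges$target), ,
                       drop = FALSE]
  rownames(tf_edges) <- NULL

  # log2 intensities for modelled (non-marker) genes
  modelled <- c(setdiff(gene_ids, marker_ids), lnc_ids)
  base <- stats::setNames(
    stats::rnorm(length(modelled), 9, 1.5) -
      2 * as.numeric(modelled %in% lnc_ids), modelled)
  # module factors: mutually orthogonal per-sample profiles, projected
  # orthogonal to the intercept, the treatment contrast and the
  # treatment x remission interaction -- planted co-expression structure
  # is patient variation, statistically separable from the planted
  # treatment response
  Z <- matrix(stats::rnorm(cfg$n_modules * n_s), cfg$n_modules)
  contrasts <- cbind(1, as.numeric(is_post),
                     as.numeric(is_post & meta$remission == "R"))
  resid <- qr.resid(qr(contrasts), t(Z))
  E_s <- t(qr.Q(qr(resid)))
  E_s <- E_s * cfg$eigengene_sd / apply(E_s, 1L, stats::sd)
  X <- matrix(base, length(modelled), n_s)
  dimnames(X) <- list(modelled, meta$sample_id)
  for (m in seq_len(cfg$n_modules)) {
    mem <- module_members[[m]]
    load <- stats::runif(length(mem), cfg$loading_range[1],
                         cfg$loading_range[2])
    # an antiphase half keeps each module's intensity mass roughly
    # balanced across samples (modules carry co-activated and
    # co-repressed genes, as in unsigned co-expression networks)
    n_neg <- round(cfg$antiphase_fraction * length(mem))
    if (n_neg > 0) {
      neg <- sample(length(mem), n_neg)
      load[neg] <- -load[neg]
    }
    X[mem, ] <- X[mem, , drop = FALSE] + outer(load, E_s[m, ])
  }
  X <- X + outer(shift[modelled], as.numeric(is_post))
  mir_centred <- mir_log - rowMeans(mir_log)
  if (nrow(mirna_edges))
    X[mirna_edges$target, ] <- X[mirna_edges$target, , drop = FALSE] +
      cfg$mirna_repression_strength *
      mir_centred[mirna_edges$regulator, , drop = FALSE]
  X <- X + matrix(stats::rnorm(length(X), 0, cfg$noise_sd), nrow(X))

  intensity <- matrix(0, length(all_gene_ids), n_s,
                      dimnames = list(all_gene_ids, meta$sample_id))
  intensity[modelled, ] <- 2^X

  # marker genes observe the mixture directly on the count-intensity scale
  sig <- stats::setNames(2^stats::rnorm(length(marker_ids), 11, 0.5),
                         marker_ids)
  noise_mult <- matrix(2^stats::rnorm(length(marker_ids) * n_s, 0,
                                      cfg$noise_sd), length(marker_ids))
  intensity[marker_ids, ] <- (sig * t(P[, marker_of[marker_ids],
                                        drop = FALSE])) * noise_mult

  # CAR transgene: absent pre-infusion, expands in remissive patients;
  # CD19 tracks the B-cell fraction
  car_level <- 2^11
  intensity["CAR", ] <- ifelse(is_post & meta$remission == "R",
                               car_level * 2^stats::rnorm(n_s, 0,
                                                          cfg$noise_sd), 0)
  intensity["CD19", ] <- 2^11.5 * P[, ct$name[1]] *
    2^stats::rnorm(n_s, 0, cfg$noise_sd)

  scale_fac <- cfg$library_size * n_s / sum(intensity)
  counts <- round(intensity * scale_fac)
  mir_int <- 2^mir_log
  mir_counts <- round(mir_int * (cfg$library_size / 10) * n_s /
                        sum(mir_int))

  lengths <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]),
                    length(all_gene_ids), replace = TRUE)
  annotation <- data.frame(
    feature_id = all_gene_ids, symbol = all_gene_ids,
    biotype = c(rep("coding", cfg$n_coding), rep("lncRNA", cfg$n_lncrna),
                "coding", "coding"),
    length_bp = lengths,
    is_tf = all_gene_ids %in% tf_ids,
    is_histone = all_gene_ids %in% histone_ids,
    is_membrane = all_gene_ids %in% membrane_ids,
    is_car = all_gene_ids == "CAR",
    is_cd19 = all_gene_ids == "CD19",
    marker_of = ifelse(all_gene_ids %in% marker_ids,
                       marker_of[all_gene_ids],
                       ifelse(all_gene_ids == "CD19", ct$name[1], NA)),
    stringsAsFactors = FALSE)
  mir_annotation <- data.frame(
    feature_id = mir_ids, symbol = mir_ids, biotype = "miRNA",
    length_bp = 22L, is_tf = FALSE, is_histone = FALSE,
    is_membrane = FALSE, is_car = FALSE, is_cd19 = FALSE,
    marker_of = NA_character_, stringsAsFactors = FALSE)

  patients <- names(cfg$remission)
  dir_chr <- function(x) ifelse(x > 0, "up", "down")
  # expected per-patient differential features: planted additive shifts,
  # mixture-driven marker changes (|expected log2 ratio| >= 1), and the
  # CAR transgene appearing post-infusion
  de_rows <- list(data.frame(
    patient = character(), feature_id = character(),
    direction = character(), expected_log2fc = numeric(),
    source = character(), stringsAsFactors = FALSE))
  if (length(de_ids))
    de_rows[[1L]] <- data.frame(
      patient = rep(patients, each = length(de_ids)),
      feature_id = rep(de_ids, cfg$n_patients),
      direction = rep(dir_chr(shift[de_ids]), cfg$n_patients),
      expected_log2fc = rep(unname(shift[de_ids]), cfg$n_patients),
      source = "planted", stringsAsFactors = FALSE)
  if (nrow(mirna_edges)) {
    # repression by a shifted regulator shifts its targets in turn
    induced <- cfg$mirna_repression_strength *
      mir_shift[mirna_edges$regulator]
    hit <- abs(induced) >= 1
    if (any(hit))
      de_rows[[length(de_rows) + 1L]] <- data.frame(
        patient = rep(patients, each = sum(hit)),
        feature_id = rep(mirna_edges$target[hit], cfg$n_patients),
        direction = rep(dir_chr(induced[hit]), cfg$n_patients),
        expected_log2fc = rep(unname(induced[hit]), cfg$n_patients),
        source = "repression", stringsAsFactors = FALSE)
  }
  marker_by_type <- split(marker_ids, marker_of[marker_ids])
  for (p in patients) {
    pre_s <- paste0(p, "_D0"); post_s <- paste0(p, "_D14")
    for (ctn in ct$name) {
      ratio <- log2((P[post_s, ctn] + 1e-12) / (P[pre_s, ctn] + 1e-12))
      feats <- marker_by_type[[ctn]]
      if (ctn == ct$name[1]) feats <- c(feats, "CD19")
      if (is.finite(ratio) && abs(ratio) >= 1)
        de_rows[[length(de_rows) + 1L]] <- data.frame(
          patient = p, feature_id = sort(feats),
          direction = dir_chr(ratio), expected_log2fc = ratio,
          source = "mixture", stringsAsFactors = FALSE)
    }
    if (cfg$remission[[p]] == "R")
      de_rows[[length(de_rows) + 1L]] <- data.frame(
        patient = p, feature_id = "CAR", direction = "up",
        expected_log2fc = NA_real_, source = "car",
        stringsAsFactors = FALSE)
  }
  de_direction <- do.call(rbind, de_rows)
  de_direction <- de_direction[order(de_direction$patient,
                                     de_direction$feature_id), ]
  rownames(de_direction) <- NULL
  dem_direction <- data.frame(
    patient = rep(patients, each = length(dem_ids)),
    feature_id = rep(dem_ids, cfg$n_patients),
    direction = rep(dir_chr(mir_shift[dem_ids]), cfg$n_patients),
    stringsAsFactors = FALSE)
  marker_panel <- data.frame(cell_type = unname(marker_of[marker_ids]),
                             feature_id = marker_ids,
                             stringsAsFactors = FALSE)
  marker_panel <- marker_panel[order(marker_panel$cell_type,
                                     marker_panel$feature_id), ]
  rownames(marker_panel) <- NULL

  truth <- list(module_of = module_of,
                de_direction = de_direction,
                dem_direction = dem_direction,
                tf_target_edges = tf_edges,
                mirna_target_edges = mirna_edges,
                true_proportions = P,
                marker_panel = marker_panel,
                gene_ids = all_gene_ids, mirna_ids = mir_ids,
                config = cfg)

  list(counts = expr_matrix(counts, "raw_count"),
       mirna_counts = expr_matrix(mir_counts, "raw_count"),
       annotation = annotation,
       mirna_annotation = mir_annotation,
       metadata = meta,
       truth = truth)
}

#' Regulator-target edge tables with decoys
#'
#' Emits the planted miRNA-target and TF-target edge lists plus a
#' configurable fraction of decoy edges. Decoy targets are drawn only from
#' features with no planted coupling to any regulator, so truth recovery
#' stays unambiguous.
#'
#' @param config The `scenario_config` used for the cohort.
#' @param truth The `truth` element returned by [generate_cohort()].
#' @param decoy_fraction Decoy rows as a fraction of true rows (default 0.2).
#' @param dir Optional directory; when given, writes `mirna_targets.tsv` and
#'   `tf_targets.tsv`.
#' @return List with `mirna_targets` and `tf_targets` data frames
#'   (columns `regulator`, `target`).
#' @export
generate_edge_tables <- function(config, truth, decoy_fraction = 0.2,
                                 dir = NULL) {
  if (decoy_fraction < 0) stop("decoy_fraction must be >= 0")
  set.seed(config$seed + 1000L)
  planted_targets <- unique(c(truth$mirna_target_edges$target,
                              truth$tf_target_edges$target))
  markerless <- setdiff(truth$gene_ids,
                        c(planted_targets, truth$marker_panel$feature_id,
                          "CAR", "CD19"))
  add_decoys <- function(edges) {
    n_decoy <- round(decoy_fraction * nrow(edges))
    if (n_decoy == 0L || nrow(edges) == 0L) return(edges)
    pool <- markerless
    if (n_decoy > length(pool))
      stop("not enough uncoupled features for the requested decoy fraction")
    decoys <- data.frame(
      regulator = sample(unique(edges$regulator), n_decoy, replace = TRUE),
      target = sample(pool, n_decoy), stringsAsFactors = FALSE)
    out <- rbind(edges, decoys)
    out[order(out$regulator, out$target), , drop = FALSE]
  }
  res <- list(mirna_targets = add_decoys(truth$mirna_target_edges),
              tf_targets = add_decoys(truth$tf_target_edges))
  rownames(res$mirna_targets) <- rownames(res$tf_targets) <- NULL
  if (!is.null(dir)) {
    data.table::fwrite(res$mirna_targets,
                       file.path(dir, "mirna_targets.tsv"), sep = "\t")
    data.table::fwrite(res$tf_targets,
                       file.path(dir, "tf_targets.tsv"), sep = "\t")
  }
  res
}

#' Gene-set collection aligned with planted modules
#'
#' Builds one pathway-style set per planted module at a configurable Jaccard
#' overlap with the module's member list, plus random background sets. With
#' `overlap = 1` each pathway equals one module; with `overlap = 0` the sets
#' are disjoint from all modules (drawn from unassigned features).
#'
#' @inheritParams generate_edge_tables
#' @param overlap Target Jaccard index between each pathway set and its
#'   module, in \[0, 1\].
#' @param n_random Number of random background sets.
#' @param path Optional GMT file path to write.
#' @return A [gene_set_collection]: named list of member vectors with a
#'   `category` attribute (`KEGG` for module-matched sets, `GO-BP` for
#'   random sets).
#' @export
generate_gene_sets <- function(config, truth, overlap = 0.8, n_random = 3L,
                               path = NULL) {
  if (overlap < 0 || overlap > 1) stop("overlap must be in [0, 1]")
  set.seed(config$seed + 2000L)
  module_of <- truth$module_of
  mods <- sort(setdiff(unique(module_of), "grey"))
  grey <- setdiff(names(module_of)[module_of == "grey"],
                  c("CAR", "CD19", truth$marker_panel$feature_id))
  sets <- list()
  cats <- character()
  for (m in mods) {
    mem <- names(module_of)[module_of == m]
    s <- length(mem)
    a <- round(2 * s * overlap / (1 + overlap))
    n_out <- s - a
    if (n_out > length(grey))
      stop("requested overlap impossible: not enough unassigned features")
    nm <- paste0("PATHWAY_", toupper(m))
    sets[[nm]] <- sort(c(sample(mem, a), sample(grey, n_out)))
    cats[nm] <- "KEGG"
  }
  for (i in seq_len(n_random)) {
    nm <- sprintf("RANDOM_SET_%d", i)
    sets[[nm]] <- sort(sample(names(module_of),
                              min(50L, length(module_of))))
    cats[nm] <- "GO-BP"
  }
  coll <- gene_set_collection(sets, cats)
  if (!is.null(path)) write_gmt(coll, path)
  coll
}

#' Write a generated cohort to a directory of flat text files
#'
#' Writes count matrices, annotation, metadata and every truth table as TSV,
#' together with a manifest (`manifest.tsv`: file, md5, seed).
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest `data.frame`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(obj, name) {
    p <- file.path(dir, name)
    if (inherits(obj, "expr_matrix")) write_expr_matrix(obj, p)
    else data.table::fwrite(obj, p, sep = "\t", quote = FALSE, na = "NA")
    p
  }
  tr <- cohort$truth
  files <- c(
    w(cohort$counts, "counts.tsv"),
    w(cohort$mirna_counts, "mirna_counts.tsv"),
    w(cohort$annotation, "annotation.tsv"),
    w(cohort$mirna_annotation, "mirna_annotation.tsv"),
    w(cohort$metadata, "metadata.tsv"),
    w(data.frame(feature_id = names(tr$module_of),
                 module = unname(tr$module_of)), "truth_modules.tsv"),
    w(tr$de_direction, "truth_de.tsv"),
    w(tr$dem_direction, "truth_dem.tsv"),
    w(tr$tf_target_edges, "truth_tf_targets.tsv"),
    w(tr$mirna_target_edges, "truth_mirna_targets.tsv"),
    w(data.frame(sample_id = rownames(tr$true_proportions),
                 tr$true_proportions, check.names = FALSE),
      "truth_proportions.tsv"),
    w(tr$marker_panel, "marker_panel.tsv"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         seed = tr$config$seed, stringsAsFactors = FALSE)
  data.table::fwrite(manifest, file.path(dir, "manifest.tsv"), sep = "\t")
  invisible(manifest)
}
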