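#' Heterogeneous regulatory network
#'
#' Typed nodes (`miRNA`, `TF`, `gene`, `lncRNA`, `pathway`) with optional
#' `direction` (`up` / `down` / `mixed` / `NA`) and module label, and typed
#' edges (`mirna_target`, `tf_target`, `coexpression`, `gene_pathway`) with
#' an optional correlation weight. Construction validates the type
#' constraints and canonicalizes ordering, so identical inputs yield
#' identical objects.
#'
#' @param nodes `data.frame` with columns `id`, `kind`, and optionally
#'   `direction`, `module`.
#' @param edges `data.frame` with columns `source`, `target`, `kind`, and
#'   optionally `weight`.
#' @return A `regulatory_network` (list with sorted `nodes` and `edges`).
#' @export
regulatory_network <- function(nodes, edges = NULL) {
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        kind = character(), weight = numeric(),
                        stringsAsFactors = FALSE)
  if (is.null(nodes$direction))
    nodes$direction <- rep(NA_character_, nrow(nodes))
  if (is.null(nodes$module)) nodes$module <- rep(NA_character_, nrow(nodes))
  if (is.null(edges$weight)) edges$weight <- rep(NA_real_, nrow(edges))
  nodes <- nodes[, c("id", "kind", "direction", "module")]
  edges <- edges[, c("source", "target", "kind", "weight")]
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- edges[order(edges$source, edges$target, edges$kind), ,
                 drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  net <- structure(list(nodes = nodes, edges = edges),
                   class = "regulatory_network")
  validate_network(net)
}

#' @rdname regulatory_network
#' @param net A `regulatory_network`.
#' @export
validate_network <- function(net) {
  nodes <- net$nodes
  edges <- net$edges
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!all(nodes$kind %in% c("miRNA", "TF", "gene", "lncRNA", "pathway")))
    stop("unknown node kind")
  if (!all(edges$kind %in% c("mirna_target", "tf_target", "coexpression",
                             "gene_pathway")))
    stop("unknown edge kind")
  if (length(setdiff(c(edges$source, edges$target), nodes$id)))
    stop("edge endpoint is not a node")
  kind_of <- stats::setNames(nodes$kind, nodes$id)
  if (any(edges$kind == "mirna_target" &
          kind_of[edges$source] != "miRNA"))
    stop("mirna_target edges must originate from miRNA nodes")
  if (any(edges$kind == "tf_target" & kind_of[edges$source] != "TF"))
    stop("tf_target edges must originate from TF nodes")
  if (any(edges$kind == "gene_pathway" &
          kind_of[edges$target] != "pathway"))
    stop("gene_pathway edges must point to pathway nodes")
  if (anyDuplicated(edges[, c("source", "target", "kind")]))
    stop("duplicate (source, target, kind) edge")
  net
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes)) print(table(x$nodes$kind))
  if (nrow(x$edges)) print(table(x$edges$kind))
  invisible(x)
}

#' Consistent differential miRNAs across remissive patients
#'
#' miRNAs called differential in every remissive patient with the same
#' direction everywhere.
#'
#' @param dem_tables Named list of per-patient DEM tables
#'   ([call_features()] output on miRNA TPM).
#' @param remissive_patients Names of the remissive patients (>= 2... at
#'   least one required; two or more for a meaningful consensus).
#' @return `data.frame` with `feature_id` and `direction`.
#' @export
select_consistent_dems <- function(dem_tables, remissive_patients) {
  if (!length(remissive_patients)) stop("empty remissive patient set")
  unknown <- setdiff(remissive_patients, names(dem_tables))
  if (length(unknown)) stop("unknown patient: ", unknown[1])
  sel <- dem_tables[remissive_patients]
  common <- sort(Reduce(intersect, lapply(sel, `[[`, "feature_id")))
  if (!length(common))
    return(data.frame(feature_id = character(), direction = character(),
                      stringsAsFactors = FALSE))
  dirs <- vapply(sel, function(tb)
    tb$direction[match(common, tb$feature_id)], character(length(common)))
  dirs <- matrix(dirs, nrow = length(common))
  same <- apply(dirs, 1L, function(d) length(unique(d)) == 1L)
  data.frame(feature_id = common[same], direction = dirs[same, 1L],
             stringsAsFactors = FALSE)
}

node_kind_from_annotation <- function(ids, annotation) {
  idx <- match(ids, annotation$feature_id)
  kind <- rep("gene", length(ids))
  kind[!is.na(idx) & annotation$is_tf[idx]] <- "TF"
  kind[!is.na(idx) & annotation$biotype[idx] == "lncRNA"] <- "lncRNA"
  kind
}

#' Assemble the miRNA-TF-gene regulatory network
#'
#' Nodes are the consistent miRNAs plus their targets restricted to the
#' DEG union; TF nodes are flagged from the annotation. Edges: miRNA-target
#' edges from the input table, TF-target edges among included nodes,
#' co-expression edges between included genes of *different* modules with
#' `|r| >= coexpr_r_min`, and gene-pathway edges from the collection
#' (isolated pathway nodes are dropped). When both expression matrices are
#' supplied, each miRNA-target edge carries the miRNA-target expression
#' correlation as its weight (reported, never used as a filter).
#'
#' @param important_mirnas `data.frame` (`feature_id`, `direction`) from
#'   [select_consistent_dems()].
#' @param mirna_targets,tf_targets Edge tables (`regulator`, `target`).
#' @param deg_union Feature ids called differential in any patient.
#' @param modules Module assignment `data.frame` (`feature_id`, `module`).
#' @param pathways A [gene_set_collection] (or `NULL` for none).
#' @param expr Gene [expr_matrix] (for co-expression edges and weights);
#'   `NULL` skips co-expression edges.
#' @param mirna_expr Optional miRNA [expr_matrix] for edge weights.
#' @param coexpr_r_min Absolute-correlation bound for cross-module
#'   co-expression edges (default 0.9).
#' @param annotation Feature annotation (TF flags, biotypes).
#' @return A [regulatory_network].
#' @export
assemble_mirna_tf_gene <- function(important_mirnas, mirna_targets,
                                   tf_targets, deg_union, modules,
                                   pathways = NULL, expr = NULL,
                                   mirna_expr = NULL, coexpr_r_min = 0.9,
                                   annotation) {
  mirs <- important_mirnas$feature_id
  mt <- mirna_targets[mirna_targets$regulator %in% mirs &
                        mirna_targets$target %in% deg_union, , drop = FALSE]
  orphan <- setdiff(mirs, mt$regulator)
  if (length(orphan))
    warning(length(orphan), " miRNA(s) without targeted DEGs kept isolated")
  genes <- sort(unique(mt$target))
  kind <- node_kind_from_annotation(genes, annotation)
  mod_of <- stats::setNames(modules$module, modules$feature_id)
  nodes <- rbind(
    data.frame(id = mirs, kind = "miRNA",
               direction = important_mirnas$direction,
               module = NA_character_, stringsAsFactors = FALSE),
    data.frame(id = genes, kind = kind,
               direction = rep(NA_character_, length(genes)),
               module = unname(mod_of[genes]), stringsAsFactors = FALSE))
  edges <- data.frame(source = mt$regulator, target = mt$target,
                      kind = rep("mirna_target", nrow(mt)),
                      weight = rep(NA_real_, nrow(mt)),
                      stringsAsFactors = FALSE)
  if (!is.null(mirna_expr) && !is.null(expr) && nrow(edges)) {
    shared <- intersect(colnames(expr), colnames(mirna_expr))
    for (i in seq_len(nrow(edges))) {
      reg <- edges$source[i]; tg <- edges$target[i]
      if (reg %in% rownames(mirna_expr) && tg %in% rownames(expr)) {
        xv <- unclass(mirna_expr)[reg, shared]
        yv <- unclass(expr)[tg, shared]
        if (stats::sd(xv) > 0 && stats::sd(yv) > 0)
          edges$weight[i] <- stats::cor(xv, yv)
      }
    }
  }
  tt <- tf_targets[tf_targets$regulator %in% genes[kind == "TF"] &
                     tf_targets$target %in% genes, , drop = FALSE]
  if (nrow(tt))
    edges <- rbind(edges, data.frame(source = tt$regulator,
                                     target = tt$target, kind = "tf_target",
                                     weight = NA_real_,
                                     stringsAsFactors = FALSE))
  if (!is.null(expr) && length(genes) >= 2L) {
    present <- intersect(genes, rownames(expr))
    if (length(present) >= 2L) {
      R <- stats::cor(t(unclass(expr)[present, , drop = FALSE]))
      mods_g <- mod_of[present]
      idx <- which(upper.tri(R) & abs(R) >= coexpr_r_min, arr.ind = TRUE)
      if (nrow(idx)) {
        a <- present[idx[, 1L]]; b <- present[idx[, 2L]]
        diff_mod <- !is.na(mods_g[a]) & !is.na(mods_g[b]) &
          mods_g[a] != mods_g[b]
        if (any(diff_mod))
          edges <- rbind(edges, data.frame(
            source = pmin(a[diff_mod], b[diff_mod]),
            target = pmax(a[diff_mod], b[diff_mod]),
            kind = "coexpression", weight = R[idx][diff_mod],
            stringsAsFactors = FALSE))
      }
    }
  }
  if (!is.null(pathways)) {
    pe <- pathway_edges(genes, pathways)
    if (nrow(pe)) {
      nodes <- rbind(nodes, data.frame(
        id = unique(pe$target), kind = "pathway",
        direction = NA_character_, module = NA_character_,
        stringsAsFactors = FALSE))
      edges <- rbind(edges, pe)
    }
  }
  regulatory_network(nodes, unique(edges))
}

pathway_edges <- function(genes, pathways) {
  rows <- list()
  for (nm in names(pathways)) {
    hit <- intersect(genes, pathways[[nm]])
    if (length(hit))
      rows[[nm]] <- data.frame(source = hit, target = nm,
                               kind = "gene_pathway", weight = NA_real_,
                               stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(source = character(), target = character(),
                      kind = character(), weight = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Assemble a within-module TF-gene-lncRNA network
#'
#' Nodes are the members of one co-expression module; co-expression edges
#' come from the supplied top-pair table restricted to the module,
#' TF-target edges connect members, and gene-pathway edges are added only
#' for the module's significantly enriched pathways.
#'
#' @param module_label Module to extract (must exist in `modules`).
#' @param modules Module assignment `data.frame`.
#' @param top_pairs Pair table from [top_corr_pairs()].
#' @param tf_targets Edge table (`regulator`, `target`).
#' @param pathways A [gene_set_collection] or `NULL`.
#' @param enrichment [fisher_enrich()] output for this module's members, or
#'   `NULL`; only sets with `fdr < sig_max` contribute pathway nodes.
#' @param annotation Feature annotation.
#' @param sig_max FDR bound for an enriched pathway (default 0.05).
#' @return A [regulatory_network].
#' @export
assemble_tf_gene_lncrna <- function(module_label, modules, top_pairs,
                                    tf_targets, pathways = NULL,
                                    enrichment = NULL, annotation,
                                    sig_max = 0.05) {
  members <- modules$feature_id[modules$module == module_label]
  if (!length(members)) stop("unknown module: ", module_label)
  kind <- node_kind_from_annotation(members, annotation)
  nodes <- data.frame(id = members, kind = kind,
                      direction = NA_character_, module = module_label,
                      stringsAsFactors = FALSE)
  edges <- data.frame(source = character(), target = character(),
                      kind = character(), weight = numeric(),
                      stringsAsFactors = FALSE)
  tp <- top_pairs[top_pairs$feature_a %in% members &
                    top_pairs$feature_b %in% members, , drop = FALSE]
  if (nrow(tp))
    edges <- rbind(edges, data.frame(
      source = pmin(tp$feature_a, tp$feature_b),
      target = pmax(tp$feature_a, tp$feature_b),
      kind = "coexpression", weight = tp$r, stringsAsFactors = FALSE))
  tt <- tf_targets[tf_targets$regulator %in% members[kind == "TF"] &
                     tf_targets$target %in% members, , drop = FALSE]
  if (nrow(tt))
    edges <- rbind(edges, data.frame(source = tt$regulator,
                                     target = tt$target, kind = "tf_target",
                                     weight = NA_real_,
                                     stringsAsFactors = FALSE))
  if (!is.null(pathways) && !is.null(enrichment)) {
    sig <- enrichment$set[enrichment$fdr < sig_max]
    if (length(sig)) {
      pe <- pathway_edges(members, pathways[names(pathways) %in% sig])
      if (nrow(pe)) {
        nodes <- rbind(nodes, data.frame(
          id = unique(pe$target), kind = "pathway",
          direction = NA_character_, module = NA_character_,
          stringsAsFactors = FALSE))
        edges <- rbind(edges, pe)
      }
    }
  }
  regulatory_network(nodes, unique(edges))
}

#' Crosstalk nodes
#'
#' Gene/TF nodes connected to at least `min_pathways` distinct pathway
#' nodes, sorted by pathway degree descending, then id.
#'
#' @param net A [regulatory_network].
#' @param min_pathways Minimum number of distinct pathways (>= 2).
#' @return Character vector of node ids.
#' @export
find_crosstalk_nodes <- function(net, min_pathways = 2L) {
  if (min_pathways < 2L) stop("min_pathways must be >= 2")
  ge <- net$edges[net$edges$kind == "gene_pathway", , drop = FALSE]
  eligible <- net$nodes$id[net$nodes$kind %in% c("gene", "TF")]
  ge <- ge[ge$source %in% eligible, , drop = FALSE]
  if (!nrow(ge)) return(character())
  deg <- tapply(ge$target, ge$source, function(x) length(unique(x)))
  deg <- deg[deg >= min_pathways]
  names(deg)[order(-deg, names(deg))]
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export / import a regulatory network
#'
#' `format = "graphml"` writes a single GraphML document with node
#' attributes (`kind`, `direction`, `module`) and edge attributes (`kind`,
#' `weight`); `format = "tsv"` writes `<prefix>_nodes.tsv` and
#' `<prefix>_edges.tsv`. Because networks are canonically sorted,
#' export -> import -> export is byte-stable.
#'
#' @param net A [regulatory_network].
#' @param path Output path (for `tsv`, used as prefix).
#' @param format `"graphml"` or `"tsv"`.
#' @return The written path(s), invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  validate_network(net)
  if (format == "tsv") {
    paths <- paste0(path, c("_nodes.tsv", "_edges.tsv"))
    data.table::fwrite(net$nodes, paths[1], sep = "\t", na = "NA",
                       quote = FALSE)
    data.table::fwrite(net$edges, paths[2], sep = "\t", na = "NA",
                       quote = FALSE)
    return(invisible(paths))
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="kind" for="node" attr.name="kind" attr.type="string"/>',
    '  <key id="direction" for="node" attr.name="direction" attr.type="string"/>',
    '  <key id="module" for="node" attr.name="module" attr.type="string"/>',
    '  <key id="ekind" for="edge" attr.name="kind" attr.type="string"/>',
    '  <key id="weight" for="edge" attr.name="weight" attr.type="double"/>',
    '  <graph id="G" edgedefault="directed">')
  for (i in seq_len(nrow(net$nodes))) {
    nd <- net$nodes[i, ]
    lines <- c(lines, sprintf('    <node id="%s">', xml_escape(nd$id)),
               sprintf('      <data key="kind">%s</data>',
                       xml_escape(nd$kind)),
               sprintf('      <data key="direction">%s</data>',
                       xml_escape(ifelse(is.na(nd$direction), "NA",
                                         nd$direction))),
               sprintf('      <data key="module">%s</data>',
                       xml_escape(ifelse(is.na(nd$module), "NA",
                                         nd$module))),
               "    </node>")
  }
  for (i in seq_len(nrow(net$edges))) {
    ed <- net$edges[i, ]
    lines <- c(lines,
               sprintf('    <edge source="%s" target="%s">',
                       xml_escape(ed$source), xml_escape(ed$target)),
               sprintf('      <data key="ekind">%s</data>',
                       xml_escape(ed$kind)),
               if (!is.na(ed$weight))
                 sprintf('      <data key="weight">%s</data>',
                         format(ed$weight, digits = 15)),
               "    </edge>")
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    nodes <- as.data.frame(data.table::fread(paste0(path, "_nodes.tsv"),
                                             sep = "\t", na.strings = "NA"))
    edges <- as.data.frame(data.table::fread(paste0(path, "_edges.tsv"),
                                             sep = "\t", na.strings = "NA"))
    if (nrow(edges) == 0L) edges <- NULL
    return(regulatory_network(nodes, edges))
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  node_els <- xml2::xml_find_all(doc, ".//node")
  get_data <- function(el, key) {
    v <- xml2::xml_text(xml2::xml_find_first(
      el, sprintf("./data[@key='%s']", key)))
    ifelse(is.na(v) | v == "NA", NA_character_, v)
  }
  nodes <- data.frame(
    id = xml2::xml_attr(node_els, "id"),
    kind = vapply(node_els, get_data, character(1), "kind"),
    direction = vapply(node_els, get_data, character(1), "direction"),
    module = vapply(node_els, get_data, character(1), "module"),
    stringsAsFactors = FALSE)
  edge_els <- xml2::xml_find_all(doc, ".//edge")
  edges <- NULL
  if (length(edge_els)) {
    wt <- vapply(edge_els, get_data, character(1), "weight")
    edges <- data.frame(
      source = xml2::xml_attr(edge_els, "source"),
      target = xml2::xml_attr(edge_els, "target"),
      kind = vapply(edge_els, get_data, character(1), "ekind"),
      weight = suppressWarnings(as.numeric(wt)),
      stringsAsFactors = FALSE)
  }
  regulatory_network(nodes, edges)
}
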