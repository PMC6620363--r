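#' Gene-set collections
#'
#' A named list of unique member identifier vectors with a per-set
#' `category` attribute (`KEGG`, `GO-BP` or `custom`).
#'
#' @param sets Named list of character vectors (no empty sets).
#' @param categories Named character vector (or single value recycled).
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, categories = "custom") {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must carry unique names")
  if (any(lengths(sets) == 0L)) stop("empty gene set not allowed")
  sets <- lapply(sets, unique)
  if (length(categories) == 1L)
    categories <- stats::setNames(rep(categories, length(sets)), names(sets))
  categories <- categories[names(sets)]
  if (anyNA(categories)) stop("every set needs a category")
  structure(sets, category = categories, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets (%s)\n", length(x),
              paste(names(table(attr(x, "category"))), collapse = ", ")))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then members, tab-separated. The
#' description field carries the category (`KEGG`, `GO-BP`, ...); unknown
#' descriptions map to `custom`.
#'
#' @param path GMT file path.
#' @return `read_gmt` returns a [gene_set_collection].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  cats <- vapply(parts, `[`, character(1), 2L)
  cats[!cats %in% c("KEGG", "GO-BP")] <- "custom"
  gene_set_collection(sets, stats::setNames(cats, names(sets)))
}

#' @rdname read_gmt
#' @param sets A [gene_set_collection].
#' @export
write_gmt <- function(sets, path) {
  cats <- attr(sets, "category")
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, cats[[nm]], sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

# one-sided over-representation tail P(X >= k), hypergeometric
hyper_tail_p <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fisher-exact over-representation test
#'
#' For each set, tests whether the query over-represents the set against
#' the background universe by the one-sided hypergeometric tail
#' `P(X >= k)`, with Benjamini-Hochberg FDR across all tested sets. Sets
#' are intersected with the background first; sets with zero background
#' overlap are skipped (recorded in the `skipped` attribute).
#'
#' @param query Feature set (subset of `background`), non-empty.
#' @param background Background universe of features.
#' @param sets A [gene_set_collection].
#' @return `data.frame` sorted by p ascending (ties lexicographic by set):
#'   `set`, `category`, `overlap` (k), `query_size` (n), `set_size` (K),
#'   `background_size` (N), `odds_ratio`, `p`, `fdr`.
#' @export
fisher_enrich <- function(query, background, sets) {
  query <- unique(query)
  background <- unique(background)
  if (!length(query)) stop("empty query")
  if (length(setdiff(query, background)))
    stop("query must be a subset of the background")
  cats <- attr(sets, "category")
  if (is.null(cats)) cats <- stats::setNames(rep("custom", length(sets)),
                                             names(sets))
  N <- length(background)
  n <- length(query)
  rows <- list()
  skipped <- character()
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], background)
    K <- length(members)
    if (K == 0L) {
      skipped <- c(skipped, nm)
      next
    }
    k <- length(intersect(query, members))
    a <- k; b <- n - k; c_ <- K - k; d <- N - K - (n - k)
    or <- if (b == 0 || c_ == 0) Inf else (a * d) / (b * c_)
    rows[[nm]] <- data.frame(set = nm, category = unname(cats[[nm]]),
                             overlap = k, query_size = n, set_size = K,
                             background_size = N, odds_ratio = or,
                             p = hyper_tail_p(k, K, n, N),
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(set = character(), category = character(),
                      overlap = integer(), query_size = integer(),
                      set_size = integer(), background_size = integer(),
                      odds_ratio = numeric(), p = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "skipped") <- skipped
    return(out)
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Top enriched terms per category
#'
#' @param table Output of [fisher_enrich()] (already p-sorted).
#' @param k_pathways Rows kept for category `KEGG` (default 20).
#' @param k_bp Rows kept for category `GO-BP` (default 15).
#' @return Reduced table; categories other than the two named ones are
#'   kept in full.
#' @export
top_terms <- function(table, k_pathways = 20L, k_bp = 15L) {
  keep <- logical(nrow(table))
  for (cat_ in unique(table$category)) {
    idx <- which(table$category == cat_)
    k <- switch(cat_, KEGG = k_pathways, `GO-BP` = k_bp, length(idx))
    keep[utils::head(idx, k)] <- TRUE
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chi-square enrichment of a feature class in modules
#'
#' Tests whether members of a feature class (e.g. histone genes) are
#' over-represented among module-assigned (non-grey) features with a
#' Pearson chi-square on the 2x2 table {class, not-class} x
#' {in module, grey}, without continuity correction, 1 df.
#'
#' @param assignment `data.frame` (`feature_id`, `module`).
#' @param class_members Feature ids of the class (subset of assigned
#'   features, non-empty).
#' @return List with `statistic`, `p`, `table` (2x2), and
#'   `low_expected` (TRUE when any expected cell < 1).
#' @export
class_chisq <- function(assignment, class_members) {
  if (!length(class_members)) stop("empty feature class")
  if (length(setdiff(class_members, assignment$feature_id)))
    stop("class members must be assigned features")
  in_class <- assignment$feature_id %in% class_members
  in_module <- assignment$module != "grey"
  tab <- rbind(class = c(sum(in_class & in_module), sum(in_class & !in_module)),
               other = c(sum(!in_class & in_module), sum(!in_class & !in_module)))
  colnames(tab) <- c("module", "grey")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    return(list(statistic = NA_real_, p = NA_real_, table = tab,
                low_expected = TRUE))
  stat <- sum((tab - expected)^2 / expected)
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       table = tab,
       low_expected = any(expected < 1))
}
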