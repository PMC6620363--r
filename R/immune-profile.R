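#' Read a marker panel
#'
#' Two-column TSV mapping a cell type (or microenvironment category) to its
#' marker features. A marker may serve only one cell type.
#'
#' @param path TSV with columns `cell_type` and `feature_id`.
#' @return `data.frame` with `cell_type`, `feature_id`.
#' @export
read_marker_panel <- function(path) {
  panel <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  validate_marker_panel(panel)
  panel
}

validate_marker_panel <- function(panel) {
  if (!all(c("cell_type", "feature_id") %in% names(panel)))
    stop("panel needs columns cell_type and feature_id")
  if (anyDuplicated(panel$feature_id))
    stop("a marker may serve only one cell type")
  invisible(panel)
}

#' Marker-based cell-type scores
#'
#' Each marker is log2-transformed (with a pseudocount) and z-scored per
#' feature across samples; the score of a cell type in a sample is the mean
#' z-score of its markers. Markers constant across samples contribute 0.
#'
#' @param expr [expr_matrix].
#' @param panel Marker panel `data.frame` (`cell_type`, `feature_id`).
#' @param pseudocount Positive regularizer for the log transform.
#' @return Matrix samples x cell types.
#' @export
cell_scores <- function(expr, panel, pseudocount = 0.1) {
  validate_marker_panel(panel)
  logm <- log2(unclass(expr) + pseudocount)
  z <- t(scale(t(logm)))
  z[!is.finite(z)] <- 0
  types <- unique(panel$cell_type)
  out <- matrix(NA_real_, ncol(expr), length(types),
                dimnames = list(colnames(expr), types))
  for (ct in types) {
    markers <- intersect(panel$feature_id[panel$cell_type == ct],
                         rownames(expr))
    if (!length(markers)) stop("no markers present for cell type: ", ct)
    out[, ct] <- colMeans(z[markers, , drop = FALSE])
  }
  out
}

#' Normalize cell scores to per-sample proportions
#'
#' Per sample, scores are shifted by subtracting the row minimum and
#' divided by the shifted total; the least-scored population therefore maps
#' to zero. A display convention — raw scores should be retained alongside.
#' Samples whose shifted scores are all zero get uniform proportions with a
#' warning.
#'
#' @param scores Matrix samples x cell types from [cell_scores()].
#' @return Proportion matrix (rows sum to 1, all entries >= 0).
#' @export
scores_to_proportions <- function(scores) {
  if (ncol(scores) < 1L) stop("need at least one cell type")
  out <- scores
  for (s in seq_len(nrow(scores))) {
    v <- scores[s, ] - min(scores[s, ])
    tot <- sum(v)
    if (tot == 0) {
      warning("flat scores in sample ", rownames(scores)[s],
              "; reporting uniform proportions")
      out[s, ] <- 1 / ncol(scores)
    } else {
      out[s, ] <- v / tot
    }
  }
  out
}

#' Membrane-gene correlation screen against anchor features
#'
#' Correlates each candidate feature with each anchor (e.g. the CAR
#' transgene and CD19) across samples and retains candidates with
#' `|r| >= r_min` (inclusive) and `p < p_max` (strict) for at least one
#' anchor. Per-anchor r and p columns are reported for all retained rows.
#'
#' @param expr [expr_matrix] containing anchors and candidates.
#' @param anchors Anchor feature ids (must be non-constant).
#' @param candidates Candidate feature ids (anchors are excluded).
#' @param r_min Absolute correlation bound, inclusive (default 0.5).
#' @param p_max P-value bound, strict (default 0.05).
#' @return `data.frame`: `feature_id`, then `r_<anchor>`, `p_<anchor>`,
#'   `pass_<anchor>` per anchor, sorted by maximal `|r|` descending.
#' @export
anchor_correlation <- function(expr, anchors, candidates,
                               r_min = 0.5, p_max = 0.05) {
  m <- unclass(expr)
  missing_anchor <- setdiff(anchors, rownames(m))
  if (length(missing_anchor)) stop("anchor not in matrix: ", missing_anchor[1])
  candidates <- setdiff(intersect(candidates, rownames(m)), anchors)
  if (!length(candidates)) stop("no candidate features present")
  for (a in anchors)
    if (stats::sd(m[a, ]) == 0) stop("anchor constant across samples: ", a)
  n <- ncol(m)
  cand_m <- m[candidates, , drop = FALSE]
  sds <- apply(cand_m, 1L, stats::sd)
  R <- matrix(NA_real_, length(candidates), length(anchors),
              dimnames = list(candidates, anchors))
  R[sds > 0, ] <- stats::cor(t(cand_m[sds > 0, , drop = FALSE]),
                             t(m[anchors, , drop = FALSE]))
  P <- cor_p(R, n)
  P[is.na(R)] <- NA_real_
  pass <- !is.na(R) & abs(R) >= r_min & P < p_max
  keep <- rowSums(pass) > 0
  out <- data.frame(feature_id = candidates[keep], stringsAsFactors = FALSE)
  for (a in anchors) {
    out[[paste0("r_", a)]] <- R[keep, a]
    out[[paste0("p_", a)]] <- P[keep, a]
    out[[paste0("pass_", a)]] <- pass[keep, a]
  }
  if (nrow(out)) {
    best <- apply(abs(R[keep, , drop = FALSE]), 1L, max, na.rm = TRUE)
    out <- out[order(-best, out$feature_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Per-category panel fold-change report
#'
#' For each panel gene and each paired (pre, post) sample pair, computes the
#' pseudocount-regularized fold change `(post + pc) / (pre + pc)` and flags
#' genes strictly exceeding `fc_threshold`.
#'
#' @param expr [expr_matrix].
#' @param panel Panel `data.frame` (`cell_type` used as category,
#'   `feature_id`).
#' @param pairs `data.frame` with columns `pre`, `post` (sample ids) and
#'   optionally `patient`.
#' @param fc_threshold Strict fold-change bound (default 2).
#' @param pseudocount Positive regularizer.
#' @return `data.frame`: `category`, `feature_id`, `patient`,
#'   `fold_change`, `flagged`.
#' @export
panel_foldchange_report <- function(expr, panel, pairs, fc_threshold = 2,
                                    pseudocount = 0.1) {
  validate_marker_panel(panel)
  m <- unclass(expr)
  bad <- setdiff(c(pairs$pre, pairs$post), colnames(m))
  if (length(bad)) stop("unknown sample in pairs: ", bad[1])
  genes <- intersect(panel$feature_id, rownames(m))
  if (is.null(pairs$patient)) pairs$patient <- paste0("pair", seq_len(nrow(pairs)))
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    fc <- (m[genes, pairs$post[i]] + pseudocount) /
          (m[genes, pairs$pre[i]] + pseudocount)
    rows[[i]] <- data.frame(
      category = panel$cell_type[match(genes, panel$feature_id)],
      feature_id = genes, patient = pairs$patient[i],
      fold_change = unname(fc), flagged = unname(fc > fc_threshold),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$category, out$feature_id, out$patient), , drop = FALSE]
  rownames(out) <- NULL
  out
}
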