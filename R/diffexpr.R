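#' Pseudocount-regularized log2 fold change
#'
#' `log2((post + pseudocount) / (pre + pseudocount))`. The pseudocount keeps
#' the ratio finite at zero expression; as it tends to 0 the value tends to
#' the raw log ratio.
#'
#' @param pre,post Non-negative expression values (vectorized).
#' @param pseudocount Positive regularizer, default 0.1 expression units.
#' @return Numeric vector of log2 fold changes (post over pre).
#' @export
log2_fold_change <- function(pre, post, pseudocount = 0.1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (any(pre < 0) || any(post < 0)) stop("expression values must be >= 0")
  log2((post + pseudocount) / (pre + pseudocount))
}

default_floor <- function(unit) {
  switch(unit, FPKM = 1, TPM = 10,
         stop("no default expression floor for unit ", unit,
              "; supply min_expression"))
}

#' Paired no-replicate differential-expression calling
#'
#' For a single patient's paired design (one pre column, one post column),
#' calls features with `|log2FC| >= min_abs_log2fc` whose larger of the two
#' values exceeds `min_expression` (strict). With no replicates per
#' condition there is no variance estimate, so calling is fold-change-based
#' with an expression floor; both thresholds are exposed.
#'
#' @param pre_matrix,post_matrix Single-column [expr_matrix] objects with
#'   identical features and unit.
#' @param min_abs_log2fc Minimum absolute log2 fold change (default 1).
#' @param min_expression Expression floor; defaults to the unit's expressed
#'   threshold (FPKM 1, TPM 10).
#' @param pseudocount Passed to [log2_fold_change()].
#' @param patient Patient label recorded in the output.
#' @return A DEG table: `patient`, `feature_id`, `log2fc`, `direction`
#'   (`up`/`down`), `pre_value`, `post_value`.
#' @export
call_features <- function(pre_matrix, post_matrix, min_abs_log2fc = 1,
                          min_expression = NULL, pseudocount = 0.1,
                          patient = NA_character_) {
  if (expr_unit(pre_matrix) != expr_unit(post_matrix))
    stop("unit mismatch: ", expr_unit(pre_matrix), " vs ",
         expr_unit(post_matrix))
  if (!identical(rownames(pre_matrix), rownames(post_matrix)))
    stop("pre and post matrices must share features in the same order")
  if (ncol(pre_matrix) != 1L || ncol(post_matrix) != 1L)
    stop("paired design expects one column per condition")
  if (is.null(min_expression))
    min_expression <- default_floor(expr_unit(pre_matrix))
  pre <- unclass(pre_matrix)[, 1L]
  post <- unclass(post_matrix)[, 1L]
  lfc <- log2_fold_change(pre, post, pseudocount)
  keep <- abs(lfc) >= min_abs_log2fc & pmax(pre, post) > min_expression
  out <- data.frame(patient = rep(patient, sum(keep)),
                    feature_id = rownames(pre_matrix)[keep],
                    log2fc = lfc[keep],
                    direction = ifelse(lfc[keep] > 0, "up", "down"),
                    pre_value = pre[keep], post_value = post[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$feature_id), , drop = FALSE]
}

#' Cross-patient DEG intersections
#'
#' @param tables Named list of DEG tables (one per patient), as produced by
#'   [call_features()].
#' @param patients Optional subset of table names to intersect
#'   (default: all).
#' @return List with `common` (features called in every selected patient)
#'   and `same_trend` (common features whose direction agrees everywhere).
#' @export
intersect_common <- function(tables, patients = NULL) {
  if (is.null(patients)) patients <- names(tables)
  unknown <- setdiff(patients, names(tables))
  if (length(unknown)) stop("unknown patient: ", unknown[1])
  if (length(patients) < 2L) stop("need at least 2 patients to intersect")
  sel <- tables[patients]
  common <- sort(Reduce(intersect, lapply(sel, `[[`, "feature_id")))
  if (!length(common))
    return(list(common = character(), same_trend = character()))
  dirs <- vapply(sel, function(tb)
    tb$direction[match(common, tb$feature_id)], character(length(common)))
  dirs <- matrix(dirs, nrow = length(common))
  same <- apply(dirs, 1L, function(d) length(unique(d)) == 1L)
  list(common = common, same_trend = common[same])
}

#' Summarize DEG composition by feature class
#'
#' @param table A DEG table.
#' @param annotation Feature annotation covering every table feature.
#' @return List of counts (`n_total`, `n_coding`, `n_lncrna`, `n_tf`,
#'   `n_up`) and fractions (`coding`, `lncrna`, `tf`, `up`); an empty table
#'   reports zero fractions with `empty = TRUE`.
#' @export
summarize_deg_classes <- function(table, annotation) {
  idx <- match(table$feature_id, annotation$feature_id)
  if (anyNA(idx))
    stop("unannotated feature: ", table$feature_id[which(is.na(idx))[1]])
  an <- annotation[idx, , drop = FALSE]
  n <- nrow(table)
  counts <- list(n_total = n,
                 n_coding = sum(an$biotype == "coding"),
                 n_lncrna = sum(an$biotype == "lncRNA"),
                 n_tf = sum(an$is_tf),
                 n_up = sum(table$direction == "up"))
  frac <- if (n == 0L) list(coding = 0, lncrna = 0, tf = 0, up = 0)
          else list(coding = counts$n_coding / n,
                    lncrna = counts$n_lncrna / n,
                    tf = counts$n_tf / n, up = counts$n_up / n)
  c(counts, frac, list(empty = n == 0L))
}

#' PLS-DA with variable importance in projection
#'
#' Fits partial least squares against a one-hot class response via the
#' iterative NIPALS algorithm on centred, unit-variance-scaled features, and
#' scores each feature by
#' `VIP_j = sqrt(p * sum_a(SS_a * (w_aj / ||w_a||)^2) / sum_a(SS_a))`,
#' where `SS_a` is the response variance explained by component `a` and
#' `w_a` its feature weight vector. By construction `mean(VIP^2) = 1`.
#'
#' @param x An [expr_matrix] (features x samples).
#' @param labels Per-sample class labels (>= 2 classes, >= 2 samples each).
#' @param n_components Number of latent components,
#'   `<= min(n_samples - 1, n_features)`.
#' @return `data.frame` with `feature_id`, `vip`, `rank`, sorted by VIP
#'   descending (ties by feature id). Constant features are dropped with a
#'   warning and excluded from the ranking.
#' @export
plsda_vip <- function(x, labels, n_components = 2L) {
  if (n_components < 1L) stop("n_components must be >= 1")
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  if (any(table(labels) < 2L)) stop("every class needs >= 2 samples")
  X <- t(unclass(x))                      # samples x features
  if (length(labels) != nrow(X)) stop("labels must match samples")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant feature(s)")
    X <- X[, sds > 0, drop = FALSE]
  }
  if (n_components > min(nrow(X) - 1L, ncol(X)))
    stop("n_components exceeds min(n_samples - 1, n_features)")
  feats <- colnames(X)
  X <- scale(X)
  Y <- stats::model.matrix(~ labels - 1)
  Y <- scale(Y, scale = FALSE)
  p <- ncol(X)
  W <- matrix(0, p, n_components)
  SS <- numeric(n_components)
  for (a in seq_len(n_components)) {
    u <- Y[, which.max(colSums(Y^2))]
    repeat {
      w <- crossprod(X, u)
      w <- w / sqrt(sum(w^2))
      t_a <- X %*% w
      q <- crossprod(Y, t_a) / sum(t_a^2)
      u_new <- Y %*% q / sum(q^2)
      if (sum((u_new - u)^2) < 1e-12 * sum(u^2) + 1e-300) break
      u <- u_new
    }
    SS[a] <- sum(q^2) * sum(t_a^2)        # response variance explained
    W[, a] <- w
    p_load <- crossprod(X, t_a) / sum(t_a^2)
    X <- X - t_a %*% t(p_load)
    Y <- Y - t_a %*% t(q)
  }
  vip <- sqrt(p * as.numeric(W^2 %*% SS) / sum(SS))
  out <- data.frame(feature_id = feats, vip = vip, stringsAsFactors = FALSE)
  out <- out[order(-out$vip, out$feature_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
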