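#' Pearson correlation with analytic two-sided p-value
#'
#' The p-value is derived from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on
#' `n - 2` degrees of freedom; `|r| = 1` maps to `p = 0`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, neither constant.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  r <- stats::cor(x, y)
  list(r = r, p = cor_p(r, n), n = n)
}

# vectorized p for a correlation matrix/vector at sample size n
cor_p <- function(r, n) {
  p <- numeric(length(r))
  sat <- abs(r) >= 1 - 1e-15
  p[sat] <- 0
  t_stat <- r[!sat] * sqrt(n - 2) / sqrt(1 - r[!sat]^2)
  p[!sat] <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  if (is.matrix(r)) p <- matrix(p, nrow(r), dimnames = dimnames(r))
  p
}

#' Soft-threshold power selection by scale-free topology fit
#'
#' For each candidate power the unsigned adjacency `|r|^beta` is formed, the
#' connectivity `k_i = sum_j |r_ij|^beta` computed, `log10(k)` binned into
#' equal-count bins, and the log-density of connectivity regressed on the
#' mean log-connectivity per bin. The signed fit index is
#' `sign(-slope) * R^2`; the smallest power reaching `target_r2` is chosen,
#' otherwise the best-fitting power is returned flagged.
#'
#' @param expr [expr_matrix] (features x samples, >= 4 samples).
#' @param candidate_powers Integer powers to evaluate.
#' @param target_r2 Required signed fit (default 0.8).
#' @param n_bins Number of equal-count connectivity bins (default 10).
#' @return List with `power`, `flagged` (TRUE when no candidate reached the
#'   target) and `diagnostics` (`power`, `fit`, `mean_k`).
#' @export
pick_soft_power <- function(expr, candidate_powers = c(1:10, 12, 14, 16),
                            target_r2 = 0.8, n_bins = 10L) {
  if (ncol(expr) < 4L) stop("need at least 4 samples")
  if (!length(candidate_powers)) stop("no candidate powers supplied")
  R <- abs(stats::cor(t(unclass(expr))))
  diag(R) <- 0
  fits <- rep(NA_real_, length(candidate_powers))
  mean_k <- rep(NA_real_, length(candidate_powers))
  for (i in seq_along(candidate_powers)) {
    k <- colSums(R^candidate_powers[i])
    mean_k[i] <- mean(k)
    k <- k[k > 0]
    if (length(unique(k)) < 2L) next      # uniform connectivity: undefined
    lk <- log10(k)
    bins <- ceiling(seq_along(lk) / (length(lk) / min(n_bins, length(lk))))
    ord <- order(lk)
    bin_of <- integer(length(lk))
    bin_of[ord] <- bins
    widths <- tapply(lk, bin_of, function(v) max(v) - min(v))
    cnt <- tabulate(bin_of)
    dens <- cnt / pmax(widths, 1e-9)
    xs <- tapply(lk, bin_of, mean)
    ok <- is.finite(dens) & dens > 0
    if (sum(ok) < 3L) next
    fit <- stats::lm(log10(dens[ok]) ~ xs[ok])
    r2 <- summary(fit)$r.squared
    fits[i] <- sign(-stats::coef(fit)[2]) * r2
  }
  diagnostics <- data.frame(power = candidate_powers, fit = fits,
                            mean_k = mean_k)
  pass <- which(!is.na(fits) & fits >= target_r2)
  if (length(pass)) {
    list(power = candidate_powers[min(pass)], flagged = FALSE,
         diagnostics = diagnostics)
  } else {
    best <- if (all(is.na(fits))) 1L else which.max(fits)
    list(power = candidate_powers[best], flagged = TRUE,
         diagnostics = diagnostics)
  }
}

#' Unsigned soft-threshold adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^power` with a zero diagonal (the convention the
#' topological-overlap transform expects).
#'
#' @param expr [expr_matrix] (features x samples, >= 3 samples).
#' @param power Soft threshold, `>= 1`.
#' @return Symmetric matrix with entries in \[0, 1\] and zero diagonal.
#' @export
adjacency <- function(expr, power) {
  if (power < 1) stop("power must be >= 1")
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  A <- abs(stats::cor(t(unclass(expr))))^power
  diag(A) <- 0
  A
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`, with
#' `l_ij = sum_u a_iu * a_uj` and `k_i = sum_u a_iu`; `TOM_ii = 1`.
#'
#' @param adj Symmetric adjacency with zero diagonal and entries in \[0, 1\].
#' @return The TOM matrix (symmetric, entries in \[0, 1\], unit diagonal).
#' @export
topological_overlap <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(diag(adj) != 0)) stop("adjacency diagonal must be zero")
  if (any(adj < 0) || any(adj > 1)) stop("adjacency entries must be in [0, 1]")
  L <- adj %*% adj
  k <- colSums(adj)
  tom <- (L + adj) / (outer(k, k, pmin) + 1 - adj)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

# WGCNA-style module color sequence, by size rank
module_color_sequence <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
    "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")
}

#' Module detection by average-linkage clustering of 1 - TOM
#'
#' Features are clustered on the dissimilarity `1 - TOM` with average
#' linkage and the tree is cut statically at `cut_height` times the maximum
#' merge height. Clusters below `min_module_size` are labelled `grey`;
#' surviving clusters are named by the standard color sequence in
#' decreasing size order (ties broken by smallest member identifier).
#'
#' @param tom A topological overlap matrix with feature dimnames.
#' @param min_module_size Smallest retained module (default 30).
#' @param cut_height Static cut as a fraction of the maximum merge height,
#'   in (0, 1\] (default 0.99).
#' @return `data.frame` with `feature_id` and `module`.
#' @export
detect_modules <- function(tom, min_module_size = 30L, cut_height = 0.99) {
  if (min_module_size < 2L) stop("min_module_size must be >= 2")
  if (cut_height <= 0 || cut_height > 1) stop("cut_height must be in (0, 1]")
  feats <- rownames(tom)
  if (is.null(feats)) feats <- as.character(seq_len(nrow(tom)))
  if (nrow(tom) == 1L)
    return(data.frame(feature_id = feats, module = "grey",
                      stringsAsFactors = FALSE))
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(h, h = cut_height * max(h$height))
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  # order by size desc, ties by lexicographically smallest member
  first_member <- vapply(keep, function(g) min(feats[cl == g]), character(1))
  keep <- keep[order(-sizes[keep], first_member)]
  colors <- module_color_sequence()
  labels <- stats::setNames(rep("grey", length(sizes)), names(sizes))
  for (i in seq_along(keep)) {
    labels[keep[i]] <- if (i <= length(colors)) colors[i]
                       else sprintf("module%d", i)
  }
  data.frame(feature_id = feats, module = unname(labels[as.character(cl)]),
             stringsAsFactors = FALSE)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' per-feature z-scored expression submatrix across samples, rescaled to
#' unit variance and sign-oriented so that its correlation with the
#' module's mean z-scored profile is non-negative.
#'
#' @param expr [expr_matrix] containing all module members.
#' @param assignment `data.frame` (`feature_id`, `module`) from
#'   [detect_modules()]; `grey` features are ignored.
#' @return Matrix modules x samples; every row has mean 0 and variance 1.
#' @export
module_eigengene <- function(expr, assignment) {
  mods <- sort(setdiff(unique(assignment$module), "grey"))
  if (!length(mods)) stop("no non-grey modules in assignment")
  E <- matrix(NA_real_, length(mods), ncol(expr),
              dimnames = list(mods, colnames(expr)))
  for (m in mods) {
    mem <- assignment$feature_id[assignment$module == m]
    sub <- unclass(expr)[mem, , drop = FALSE]
    sds <- apply(sub, 1L, stats::sd)
    if (all(sds == 0)) stop("module has only constant features: ", m)
    if (any(sds == 0)) {
      warning("dropping ", sum(sds == 0), " constant feature(s) in ", m)
      sub <- sub[sds > 0, , drop = FALSE]
    }
    z <- t(scale(t(sub)))
    sv <- svd(z, nu = 0L, nv = 1L)
    e <- sv$v[, 1L]
    if (stats::cor(e, colMeans(z)) < 0) e <- -e
    E[m, ] <- e / stats::sd(e)
  }
  E
}

#' Pathway activity scores
#'
#' Per-sample mean z-score of a gene set's members: a transparent summary
#' profile used to correlate modules with pathway activity.
#'
#' @param expr [expr_matrix].
#' @param sets A [gene_set_collection] (or named list of feature vectors).
#' @return Matrix sets x samples.
#' @export
pathway_activity <- function(expr, sets) {
  m <- unclass(expr)
  z <- t(scale(t(m)))
  z[!is.finite(z)] <- 0                   # constant features contribute 0
  out <- matrix(NA_real_, length(sets), ncol(m),
                dimnames = list(names(sets), colnames(m)))
  for (i in seq_along(sets)) {
    mem <- intersect(sets[[i]], rownames(m))
    if (!length(mem)) stop("gene set has no features in the matrix: ",
                           names(sets)[i])
    out[i, ] <- colMeans(z[mem, , drop = FALSE])
  }
  out
}

#' Module-feature correlation screen
#'
#' Correlates each module eigengene with each external per-sample profile
#' (pathway activity scores, traits) and flags associations with
#' `r > r_min` and `p < p_max`.
#'
#' @param eigengenes Matrix modules x samples ([module_eigengene()]).
#' @param feature_profiles Matrix profiles x samples, same sample order.
#' @param r_min,p_max Significance thresholds (defaults 0.9 and 1e-6).
#' @return `data.frame` with `module`, `profile`, `r`, `p`, `significant`.
#' @export
module_feature_correlation <- function(eigengenes, feature_profiles,
                                       r_min = 0.9, p_max = 1e-6) {
  if (!identical(colnames(eigengenes), colnames(feature_profiles)))
    stop("eigengenes and profiles must share the same samples")
  n <- ncol(eigengenes)
  R <- stats::cor(t(eigengenes), t(feature_profiles))
  P <- cor_p(R, n)
  out <- data.frame(
    module = rep(rownames(eigengenes), ncol(R)),
    profile = rep(colnames(R), each = nrow(R)),
    r = as.numeric(R), p = as.numeric(P), stringsAsFactors = FALSE)
  out$significant <- out$r > r_min & out$p < p_max
  out <- out[order(out$module, out$profile), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top correlated cross-set pairs
#'
#' All pairs (a in `set_a`, b in `set_b`) with `r > r_min` and `p < p_max`,
#' ranked by `|r|` descending (ties: smaller p, then lexicographic pair id)
#' and truncated to `n_top`. Typical use: top gene-lncRNA pairs.
#'
#' @param set_a,set_b Disjoint feature identifier vectors.
#' @param expr [expr_matrix] containing both sets.
#' @param n_top Maximum number of returned pairs (default 200).
#' @param r_min,p_max Thresholds (defaults 0.9, 1e-6).
#' @return `data.frame` with `feature_a`, `feature_b`, `r`, `p`; attribute
#'   `n_passing` records how many pairs passed before truncation.
#' @export
top_corr_pairs <- function(set_a, set_b, expr, n_top = 200L,
                           r_min = 0.9, p_max = 1e-6) {
  if (length(intersect(set_a, set_b))) stop("sets must be disjoint")
  if (n_top < 1L) stop("n_top must be >= 1")
  set_a <- intersect(set_a, rownames(expr))
  set_b <- intersect(set_b, rownames(expr))
  empty <- data.frame(feature_a = character(), feature_b = character(),
                      r = numeric(), p = numeric(), stringsAsFactors = FALSE)
  if (!length(set_a) || !length(set_b)) {
    attr(empty, "n_passing") <- 0L
    return(empty)
  }
  n <- ncol(expr)
  R <- stats::cor(t(unclass(expr)[set_a, , drop = FALSE]),
                  t(unclass(expr)[set_b, , drop = FALSE]))
  P <- cor_p(R, n)
  pass <- which(R > r_min & P < p_max, arr.ind = TRUE)
  if (!nrow(pass)) {
    attr(empty, "n_passing") <- 0L
    return(empty)
  }
  out <- data.frame(feature_a = set_a[pass[, 1L]],
                    feature_b = set_b[pass[, 2L]],
                    r = R[pass], p = P[pass], stringsAsFactors = FALSE)
  out <- out[order(-abs(out$r), out$p, out$feature_a, out$feature_b), ,
             drop = FALSE]
  n_passing <- nrow(out)
  out <- utils::head(out, n_top)
  rownames(out) <- NULL
  attr(out, "n_passing") <- n_passing
  out
}
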