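#' Fragments per kilobase per million mapped reads
#'
#' `FPKM_gs = 1e9 * C_gs / (N_s * L_g)` where `N_s` is the per-sample total
#' assigned count and `L_g` the feature length in bp. No effective-length
#' correction is applied.
#'
#' @param counts An [expr_matrix] in `raw_count` unit.
#' @param annotation Feature annotation (see [read_annotation]) providing
#'   `length_bp` for every matrix feature.
#' @return An [expr_matrix] in `FPKM` unit.
#' @export
#' @examples
#' m <- expr_matrix(matrix(c(100, 999900), 2, 1,
#'                  dimnames = list(c("a", "b"), "s1")), "raw_count")
#' an <- data.frame(feature_id = c("a", "b"), symbol = c("a", "b"),
#'                  biotype = "coding", length_bp = c(1000L, 1000L),
#'                  is_tf = FALSE, is_histone = FALSE, is_membrane = FALSE,
#'                  is_car = FALSE, is_cd19 = FALSE, marker_of = NA)
#' fpkm(m, an)["a", "s1"]  # 100
fpkm <- function(counts, annotation) {
  if (expr_unit(counts) != "raw_count")
    stop("fpkm() requires raw counts, got unit ", expr_unit(counts))
  N <- colSums(counts)
  if (any(N <= 0))
    stop("zero-total sample: ", colnames(counts)[which(N <= 0)[1]])
  L <- feature_lengths(counts, annotation)
  vals <- 1e9 * sweep(unclass(counts), 2, N, "/") / L
  expr_matrix(vals, "FPKM")
}

#' Transcripts per million
#'
#' Length-normalized rates `C_gs / L_g` rescaled so each sample sums to 1e6.
#' For miRNA matrices all lengths may be equal, in which case TPM reduces to
#' counts-per-million.
#'
#' @inheritParams fpkm
#' @return An [expr_matrix] in `TPM` unit; every sample column sums to 1e6.
#' @export
tpm <- function(counts, annotation) {
  if (expr_unit(counts) != "raw_count")
    stop("tpm() requires raw counts, got unit ", expr_unit(counts))
  N <- colSums(counts)
  if (any(N <= 0))
    stop("zero-total sample: ", colnames(counts)[which(N <= 0)[1]])
  L <- feature_lengths(counts, annotation)
  rate <- unclass(counts) / L
  vals <- sweep(rate, 2, colSums(rate), "/") * 1e6
  expr_matrix(vals, "TPM")
}

#' Filter to expressed features
#'
#' Retains features whose value is strictly greater than `threshold` in at
#' least `min_samples` samples; feature order is preserved. The operation is
#' idempotent.
#'
#' @param x An [expr_matrix] in `FPKM` or `TPM` unit.
#' @param threshold Expression threshold (strict `>`), e.g. 1 for gene FPKM
#'   or 10 for miRNA TPM.
#' @param min_samples Minimum number of samples exceeding the threshold.
#' @return The filtered [expr_matrix].
#' @export
filter_expressed <- function(x, threshold, min_samples = 1L) {
  if (!expr_unit(x) %in% c("FPKM", "TPM"))
    stop("filter_expressed() expects FPKM or TPM, got ", expr_unit(x))
  if (threshold < 0) stop("threshold must be >= 0")
  if (min_samples < 1L || min_samples > ncol(x))
    stop("min_samples must be in [1, n_samples]")
  keep <- rowSums(unclass(x) > threshold) >= min_samples
  x[keep, , drop = FALSE]
}

#' Features above a threshold in every sample
#'
#' @param x An [expr_matrix] in `FPKM` unit.
#' @param threshold Strict lower bound that must hold in all samples
#'   (default 100).
#' @return Character vector of feature identifiers.
#' @export
highly_expressed <- function(x, threshold = 100) {
  if (expr_unit(x) != "FPKM")
    stop("highly_expressed() expects FPKM, got ", expr_unit(x))
  if (nrow(x) == 0L) return(character())
  rownames(x)[rowSums(unclass(x) > threshold) == ncol(x)]
}

#' Abundance share of the top-k features per sample
#'
#' Per sample, features are sorted by value descending (ties broken by
#' feature identifier ascending) and the ratio sum(top k) / sum(all) is
#' reported. An all-zero sample yields share 0 and a warning record.
#'
#' @param x An [expr_matrix] (typically miRNA TPM).
#' @param k Number of top features, `>= 1`.
#' @return List with `share` (named per-sample numeric in \[0, 1\]),
#'   `top_features` (per-sample character vectors) and `warnings`
#'   (sample ids whose total abundance was zero).
#' @export
top_abundance_share <- function(x, k) {
  if (k < 1L) stop("k must be >= 1")
  k <- min(as.integer(k), nrow(x))
  m <- unclass(x)
  feats <- rownames(m)
  share <- stats::setNames(numeric(ncol(m)), colnames(m))
  tops <- stats::setNames(vector("list", ncol(m)), colnames(m))
  warn <- character()
  for (s in seq_len(ncol(m))) {
    v <- m[, s]
    ord <- order(-v, feats)
    tops[[s]] <- feats[ord[seq_len(k)]]
    tot <- sum(v)
    if (tot <= 0) {
      share[s] <- 0
      warn <- c(warn, colnames(m)[s])
    } else {
      share[s] <- sum(v[ord[seq_len(k)]]) / tot
    }
  }
  list(share = share, top_features = tops, warnings = warn)
}
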