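# shared fixture builders and independent oracles

make_expr <- function(values, unit = "FPKM", features = NULL,
                      samples = NULL) {
  m <- as.matrix(values)
  if (is.null(rownames(m)))
    rownames(m) <- if (is.null(features)) sprintf("g%02d", seq_len(nrow(m)))
                   else features
  if (is.null(colnames(m)))
    colnames(m) <- if (is.null(samples)) sprintf("s%d", seq_len(ncol(m)))
                   else samples
  expr_matrix(m, unit)
}

make_annotation <- function(ids, biotype = "coding", length_bp = 1000L,
                            is_tf = FALSE, marker_of = NA_character_) {
  data.frame(feature_id = ids, symbol = ids,
             biotype = rep_len(biotype, length(ids)),
             length_bp = rep_len(length_bp, length(ids)),
             is_tf = rep_len(is_tf, length(ids)),
             is_histone = FALSE, is_membrane = FALSE, is_car = FALSE,
             is_cd19 = FALSE, marker_of = rep_len(marker_of, length(ids)),
             stringsAsFactors = FALSE)
}

# small 3-patient scenario (fast; supports up to 3 planted modules)
small_scenario <- function(seed = 1L, ...) {
  args <- list(
    n_patients = 3L,
    remission = c("P1" = "R", "P2" = "NR", "P3" = "R"),
    n_coding = 80L, n_lncrna = 20L, n_mirna = 10L,
    n_tf = 8L, n_histone = 4L, n_membrane = 8L,
    n_modules = 2L, module_sizes = c(20L, 20L),
    cell_types = data.frame(name = c("B_cell", "T_cell"), n_markers = 4L),
    proportions = matrix(rep(c(0.7, 0.3, 0.4, 0.6), 3), 6, 2,
                         byrow = TRUE,
                         dimnames = list(NULL, c("B_cell", "T_cell"))),
    seed = seed)
  user <- list(...)
  args[names(user)] <- user
  do.call(scenario_config, args)
}

# triple-loop topological-overlap oracle
tom_oracle <- function(adj) {
  n <- nrow(adj)
  out <- diag(n)
  k <- rowSums(adj)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) l <- l + adj[i, u] * adj[u, j]
    out[i, j] <- (l + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
  }
  out
}

# hypergeometric upper-tail by direct binomial-coefficient enumeration
hyper_tail_oracle <- function(k, K, n, N) {
  ks <- k:min(K, n)
  ks <- ks[ks >= max(0, n - (N - K))]
  if (!length(ks)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# two-sided t-tail by numerical quadrature of the density
t_tail_quadrature <- function(t_abs, df) {
  dens <- function(t) gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
    (1 + t^2 / df)^(-(df + 1) / 2)
  2 * stats::integrate(dens, t_abs, Inf, rel.tol = 1e-10)$value
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

run_default_de <- function(cohort) {
  fp <- fpkm(cohort$counts, cohort$annotation)
  lapply(stats::setNames(nm = unique(cohort$metadata$patient)), function(p)
    call_features(fp[, paste0(p, "_D0"), drop = FALSE],
                  fp[, paste0(p, "_D14"), drop = FALSE], patient = p))
}

detect_default_modules <- function(cohort, power = 6, min_size = 30L,
                                   cut = 0.99) {
  fp <- fpkm(cohort$counts, cohort$annotation)
  lg <- log2(unclass(filter_expressed(fp, 1, 1)) + 1)
  lg <- lg[apply(lg, 1L, stats::sd) > 0, , drop = FALSE]
  em <- expr_matrix(lg, "log2")
  detect_modules(topological_overlap(adjacency(em, power)), min_size, cut)
}
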