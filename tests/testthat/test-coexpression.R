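test_that("pearson_with_p matches the quadrature oracle and edge cases", {
  x <- 1:10
  expect_equal(pearson_with_p(x, x), list(r = 1, p = 0, n = 10))
  # orthogonal by construction: r = 0 gives p = 1
  y <- c(1, -1, 1, -1, 1, -1)
  expect_equal(pearson_with_p(rep(c(1, 1, -1, -1), length.out = 6) - 0,
                              y)$p, 1, tolerance = 1e-12)

  set.seed(31)
  for (i in 1:5) {
    a <- rnorm(10); b <- 0.9 * a + rnorm(10, sd = 0.4)
    res <- pearson_with_p(a, b)
    t_abs <- abs(res$r) * sqrt(8) / sqrt(1 - res$r^2)
    expect_equal(res$p, t_tail_quadrature(t_abs, 8), tolerance = 1e-6)
  }
  expect_error(pearson_with_p(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_with_p(1:2, 2:1), "at least 3")
})

test_that("adjacency is |r|^beta with zero diagonal", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(1, 3, 2, 4))
  em <- make_expr(x, "log2")
  a1 <- adjacency(em, 1)
  expect_equal(a1["a", "b"], 1)          # r = -1
  expect_equal(diag(a1), rep(0, 3), ignore_attr = TRUE)
  a2 <- adjacency(em, 2)
  expect_equal(a2["a", "c"], cor(x["a", ], x["c", ])^2)
  expect_error(adjacency(em, 0.5), "power")
  expect_error(adjacency(make_expr(x[, 1:2], "log2"), 2), "3 samples")
})

test_that("topological overlap equals the triple-loop oracle", {
  # hand-checked 3-node case
  adj <- matrix(c(0, 1, 1, 1, 0, 0, 1, 0, 0), 3, 3)
  tom <- topological_overlap(adj)
  expect_equal(tom[1, 2], 1)
  expect_equal(tom[2, 3], 0.5)

  zero <- matrix(0, 4, 4)
  expect_equal(topological_overlap(zero) - diag(4), matrix(0, 4, 4))

  set.seed(32)
  for (i in 1:10) {
    n <- sample(2:10, 1)
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    expect_equal(topological_overlap(a), tom_oracle(a), tolerance = 1e-12)
  }
  expect_error(topological_overlap(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("module detection resolves planted blocks and degenerate input", {
  blocks <- matrix(0, 60, 60)
  blocks[1:30, 1:30] <- 1
  blocks[31:60, 31:60] <- 1
  diag(blocks) <- 0
  dimnames(blocks) <- list(sprintf("g%02d", 1:60), sprintf("g%02d", 1:60))
  mods <- detect_modules(topological_overlap(blocks), 30, 0.99)
  expect_setequal(unique(mods$module), c("turquoise", "blue"))
  expect_equal(length(unique(mods$module[1:30])), 1L)

  all_grey <- detect_modules(topological_overlap(blocks), 61, 0.99)
  expect_true(all(all_grey$module == "grey"))

  single <- matrix(1, 1, 1, dimnames = list("g1", "g1"))
  expect_equal(detect_modules(single, 2, 0.5)$module, "grey")
})

test_that("module detection is invariant to feature input order", {
  coh <- generate_cohort(small_scenario(seed = 7))
  lg <- log2(unclass(coh$counts) + 0.5)
  lg <- lg[apply(lg, 1L, sd) > 0, ]
  em <- make_expr(lg, "log2")
  m1 <- detect_modules(topological_overlap(adjacency(em, 6)), 10, 0.99)
  set.seed(1)
  perm <- sample(nrow(lg))
  em2 <- make_expr(lg[perm, ], "log2")
  m2 <- detect_modules(topological_overlap(adjacency(em2, 6)), 10, 0.99)
  joined <- merge(m1, m2, by = "feature_id")
  expect_equal(ari(joined$module.x, joined$module.y), 1)
})

test_that("module eigengenes match an independent eigendecomposition", {
  set.seed(33)
  # identical profiles: eigengene equals the common z-scored profile
  prof <- rnorm(6)
  m <- matrix(rep(prof, each = 4), 4, byrow = FALSE) *
    c(1, 2, 3, 4) + c(0, 5, 1, 2)
  dimnames(m) <- list(paste0("g", 1:4), paste0("s", 1:6))
  asn <- data.frame(feature_id = paste0("g", 1:4), module = "turquoise")
  eg <- module_eigengene(make_expr(m, "log2"), asn)
  zprof <- as.numeric(scale(prof))
  expect_equal(abs(cor(eg["turquoise", ], zprof)), 1, tolerance = 1e-10)
  expect_gte(cor(eg["turquoise", ], colMeans(t(scale(t(m))))), 0)
  expect_equal(mean(eg["turquoise", ]), 0, tolerance = 1e-12)
  expect_equal(sd(eg["turquoise", ]), 1, tolerance = 1e-12)

  # duplicating a feature does not move the eigengene
  m2 <- rbind(m, g5 = m[1, ])
  asn2 <- rbind(asn, data.frame(feature_id = "g5", module = "turquoise"))
  eg2 <- module_eigengene(make_expr(m2, "log2"), asn2)
  expect_equal(eg2, eg, tolerance = 1e-10)

  # dense eigensolver oracle on a 4-feature toy
  x <- matrix(rnorm(4 * 8), 4, 8,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:8)))
  z <- t(scale(t(x)))
  ev <- eigen(crossprod(z))$vectors[, 1]
  eg3 <- module_eigengene(make_expr(x, "log2"),
                          data.frame(feature_id = paste0("g", 1:4),
                                     module = "blue"))
  expect_equal(abs(cor(eg3["blue", ], ev)), 1, tolerance = 1e-10)

  const <- matrix(1, 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4)))
  expect_error(module_eigengene(make_expr(const, "log2"),
                                data.frame(feature_id = c("a", "b"),
                                           module = "red")), "red")
})

test_that("module-profile correlation flags only genuine associations", {
  coh <- generate_cohort(small_scenario(seed = 8, noise_sd = 0,
                                        antiphase_fraction = 0))
  lg <- log2(unclass(coh$counts) + 0.5)
  lg <- lg[apply(lg, 1L, sd) > 0, ]
  em <- make_expr(lg, "log2")
  mo <- coh$truth$module_of
  asn <- data.frame(feature_id = names(mo),
                    module = ifelse(mo == "grey", "grey", mo))
  asn <- asn[asn$feature_id %in% rownames(lg), ]
  eg <- module_eigengene(em, asn)
  sets <- list(own = intersect(names(mo)[mo == "planted1"], rownames(lg)))
  act <- pathway_activity(em, sets)
  res <- module_feature_correlation(eg, act, r_min = 0.9, p_max = 1e-6)
  expect_true(res$significant[res$module == "planted1"])

  # permuted samples on one side: the strict joint flag never fires
  set.seed(34)
  flags <- replicate(100, {
    act_p <- act[, sample(ncol(act)), drop = FALSE]
    colnames(act_p) <- colnames(act)
    sum(module_feature_correlation(eg, act_p)$significant)
  })
  expect_lte(mean(flags), 0.01)

  # impossible bound
  res2 <- module_feature_correlation(eg, act, r_min = 1.01)
  expect_false(any(res2$significant))
  expect_error(module_feature_correlation(eg, act[, 1:3, drop = FALSE]),
               "same samples")
})

test_that("top correlated pairs rank, truncate and stay calibrated", {
  set.seed(35)
  base <- matrix(rnorm(3 * 8), 3, 8)
  planted <- rbind(base + rnorm(24, sd = 1e-4), matrix(rnorm(2 * 8), 2, 8))
  x <- rbind(base, planted)
  rownames(x) <- c(paste0("a", 1:3), paste0("b", 1:5))
  colnames(x) <- paste0("s", 1:8)
  em <- make_expr(x, "log2")
  res <- top_corr_pairs(paste0("a", 1:3), paste0("b", 1:5), em, 10,
                        r_min = 0.9, p_max = 1e-6)
  expect_equal(nrow(res), 3)
  expect_setequal(paste(res$feature_a, res$feature_b),
                  c("a1 b1", "a2 b2", "a3 b3"))
  one <- top_corr_pairs(paste0("a", 1:3), paste0("b", 1:5), em, 1,
                        r_min = 0.9, p_max = 1e-6)
  expect_equal(nrow(one), 1)
  expect_equal(attr(one, "n_passing"), 3L)
  expect_equal(one$r, res$r[1])

  expect_error(top_corr_pairs(c("a1"), c("a1", "b1"), em), "disjoint")
  empty <- top_corr_pairs(character(), paste0("b", 1:5), em)
  expect_equal(nrow(empty), 0)

  # null calibration at a moderate threshold: pass rate ~ P(r > 0, p < .05)
  set.seed(36)
  hits <- 0; total <- 0
  for (i in 1:200) {
    xn <- matrix(rnorm(6 * 8), 6, 8,
                 dimnames = list(c(paste0("u", 1:3), paste0("v", 1:3)),
                                 paste0("s", 1:8)))
    r <- top_corr_pairs(paste0("u", 1:3), paste0("v", 1:3),
                        make_expr(xn, "log2"), 9, r_min = 0,
                        p_max = 0.05)
    hits <- hits + attr(r, "n_passing"); total <- total + 9
  }
  p_hat <- hits / total
  se <- sqrt(0.025 * 0.975 / total)
  expect_lt(abs(p_hat - 0.025), 3 * se + 0.005)
})

test_that("soft-power selection follows its stated criterion", {
  # all pairwise |r| identical: every power degenerate, flagged fallback
  x <- rbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10),
             c = c(3, 6, 9, 12, 15), d = c(1, 2, 3, 4, 5) * 4)
  sel <- suppressWarnings(pick_soft_power(make_expr(x, "log2"),
                                          candidate_powers = c(2, 4)))
  expect_true(sel$flagged)

  set.seed(37)
  y <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:6)))
  single <- pick_soft_power(make_expr(y, "log2"), candidate_powers = 6)
  expect_equal(single$power, 6)

  # chosen power matches independent re-evaluation of the same criterion
  hub <- matrix(rnorm(30 * 8, sd = 0.3), 30, 8)
  hub[1, ] <- rnorm(8, sd = 2)
  for (i in 2:10) hub[i, ] <- hub[1, ] * runif(1, 0.5, 1) +
    rnorm(8, sd = 0.5)
  dimnames(hub) <- list(sprintf("g%02d", 1:30), paste0("s", 1:8))
  em <- make_expr(hub, "log2")
  sel2 <- pick_soft_power(em, candidate_powers = 1:8, target_r2 = 0.8)
  fits <- sel2$diagnostics$fit
  if (any(!is.na(fits) & fits >= 0.8)) {
    expect_equal(sel2$power, min(sel2$diagnostics$power[
      !is.na(fits) & fits >= 0.8]))
    expect_false(sel2$flagged)
  } else {
    expect_equal(sel2$power, sel2$diagnostics$power[which.max(fits)])
    expect_true(sel2$flagged)
  }
})
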