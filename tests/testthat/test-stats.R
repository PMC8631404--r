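test_that("variability score is CV over n, zero iff CV is zero", {
  expect_equal(variability_score(c(5, 5, 5, 5)), 0)
  expect_equal(variability_score(c(1, 3)), sd(c(1, 3)) / 2 / 2)
  expect_equal(variability_score(c(1, 3)), 0.3536, tolerance = 1e-3)
  expect_true(is.na(variability_score(1)))
  expect_true(is.na(variability_score(c(-1, 1))))  # zero mean
})

test_that("specificity index is a log-ratio and antisymmetric", {
  cc <- list(cortex = rep(3, 4), striatum = rep(3, 5))
  expect_equal(specificity_index(cc, "cortex"), 0)
  cc2 <- list(target = exp(1) * c(2, 5), other = c(2, 5))
  expect_equal(specificity_index(cc2, "target"), 1)
  expect_equal(specificity_index(cc2, "other"), -1)
  set.seed(51)
  cc3 <- list(a = rlnorm(10), b = rlnorm(15))
  expect_equal(specificity_index(cc3, "a"), -specificity_index(cc3, "b"))
  expect_warning(
    specificity_index(list(a = c(1, -2), b = c(1, 1)), "a"),
    "nonpositive")
})

test_that("top-percentile selection uses the overall quantile, strictly", {
  e <- data.frame(canonical_gene = sprintf("G%03d", 1:100),
                  concentration_uM = 1:100,
                  cell_type = rep(c("n", "a"), 50),
                  stringsAsFactors = FALSE)
  top <- top_percentile_proteins(e, "cell_type", q = 0.99)
  expect_equal(unname(unlist(top)), "G100")
  flat <- e
  flat$concentration_uM <- 1
  expect_equal(sum(lengths(top_percentile_proteins(flat, "cell_type", 0.99))),
               0L)
  all_in <- top_percentile_proteins(e, "cell_type", q = 0)
  expect_equal(sum(lengths(all_in)), 100)
})

test_that("pairwise correlations use only each pair's shared proteins", {
  set.seed(61)
  base <- data.frame(canonical_gene = sprintf("G%02d", 1:30),
                     concentration_uM = rlnorm(30, 0, 1),
                     study_id = "s1", stringsAsFactors = FALSE)
  copy <- base
  copy$study_id <- "s2"
  disjoint <- data.frame(canonical_gene = sprintf("H%02d", 1:10),
                         concentration_uM = rlnorm(10),
                         study_id = "s3", stringsAsFactors = FALSE)
  ct <- correlation_tables(rbind(base, copy, disjoint), "study_id")
  expect_equal(ct$r["s1", "s2"], 1)
  expect_equal(ct$n_common["s1", "s2"], 30L)
  expect_equal(ct$n_common["s1", "s3"], 0L)
  expect_true(is.na(ct$r["s1", "s3"]))
  # identical copies of one study give an all-ones table
  trio <- rbind(base, copy, transform(base, study_id = "s4"))
  r3 <- correlation_tables(trio, "study_id")$r
  expect_true(all(r3 == 1))
})

test_that("pairwise correlation tracks a known latent correlation", {
  set.seed(62)
  n <- 500
  z <- rnorm(n)
  a <- 0.8 * z + sqrt(1 - 0.64) * rnorm(n)
  e <- rbind(
    data.frame(canonical_gene = sprintf("G%03d", 1:n),
               concentration_uM = exp(z), study_id = "x"),
    data.frame(canonical_gene = sprintf("G%03d", 1:n),
               concentration_uM = exp(a), study_id = "y"))
  r <- correlation_tables(e, "study_id")$r["x", "y"]
  expect_gt(r, 0.7)
  expect_lt(r, 0.9)
})

test_that("median-equality battery runs Conover only after KW rejection", {
  same <- list(a = 1:10, b = 1:10, c = 1:10)
  res_null <- median_equality_battery(lapply(same, as.numeric))
  expect_false(res_null$rejected)
  expect_null(res_null$conover_p_holm)

  shifted <- list(a = as.numeric(1:10), b = as.numeric(1:10),
                  c = as.numeric(101:110))
  res <- median_equality_battery(shifted)
  expect_true(res$rejected)
  holm <- res$conover_p_holm
  expect_lt(holm["a", "c"], 0.05)
  expect_lt(holm["b", "c"], 0.05)
  expect_gt(holm["a", "b"], 0.05)
  # Holm-adjusted p-values dominate raw ones and are monotone
  raw <- res$conover_p_raw[upper.tri(res$conover_p_raw)]
  adj <- holm[upper.tri(holm)]
  expect_true(all(adj >= raw))
  ord <- order(raw)
  expect_true(all(diff(adj[ord]) >= -1e-12))
  expect_error(median_equality_battery(list(a = 1:5, b = 1:5)),
               "two-sample")
})

test_that("Conover p-values match an independent rank-formula oracle", {
  # direct transcription of the rank-statistic definition, computed
  # separately from the package's vectorized implementation
  set.seed(63)
  groups <- list(a = rnorm(8), b = rnorm(12, 1), c = rnorm(10, 2))
  res <- median_equality_battery(groups)
  values <- unlist(groups, use.names = FALSE)
  glab <- rep(names(groups), lengths(groups))
  N <- length(values)
  k <- 3
  rk <- rank(values)
  H <- unname(kruskal.test(values, factor(glab))$statistic)
  s2 <- (sum(rk^2) - N * (N + 1)^2 / 4) / (N - 1)
  rb <- tapply(rk, glab, mean)
  nn <- tapply(rk, glab, length)
  tstat <- (rb[["a"]] - rb[["b"]]) /
    sqrt(s2 * ((N - 1 - H) / (N - k)) * (1 / nn[["a"]] + 1 / nn[["b"]]))
  expect_equal(res$conover_p_raw["a", "b"],
               2 * pt(abs(tstat), N - k, lower.tail = FALSE))
})

test_that("two-group battery separates location from scale effects", {
  set.seed(71)
  b <- rnorm(60)
  ident <- two_group_battery(b, b)
  expect_equal(ident$dbm_ovs, 0)
  expect_equal(ident$mwu_p, 1)

  shifted <- two_group_battery(b + 10, b)
  expect_gt(shifted$dbm_ovs, 0)
  expect_lt(shifted$mwu_p, 0.001)
  expect_lt(shifted$ks_p, 0.001)
  expect_gt(shifted$brown_forsythe_p, 0.05)
  expect_gt(shifted$fligner_killeen_p, 0.05)

  scaled <- two_group_battery(3 * (b - mean(b)) + mean(b), b)
  expect_lt(scaled$brown_forsythe_p, 0.01)
  expect_lt(scaled$fligner_killeen_p, 0.01)
  expect_gt(scaled$mwu_p, 0.05)

  expect_error(two_group_battery(1:3, 1:10), "at least 5")
})

test_that("DBM/OVS uses the whisker span of both groups", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(11, 12, 13, 14, 15)
  res <- two_group_battery(a, b)
  expect_equal(res$dbm_ovs, abs(3 - 13) / (15 - 1))
  flat <- two_group_battery(rep(2, 5), rep(2, 6))
  expect_true(is.na(flat$dbm_ovs))  # zero spread is flagged as undefined
})

test_that("permutation battery is deterministic and powered for shifts", {
  set.seed(81)
  a <- rnorm(300)
  b <- rnorm(300, mean = 2)  # 2 pooled-SD location shift
  r1 <- permutation_battery(a, b, n = 100, reps = 30, seed = 9,
                            mode = "treatment")
  r2 <- permutation_battery(a, b, n = 100, reps = 30, seed = 9,
                            mode = "treatment")
  expect_identical(r1, r2)
  expect_gt(r1[["mwu"]], 0.99)
  expect_error(permutation_battery(a, b, n = 0), "invalid")
})

test_that("differential selection applies the fold-change thresholds", {
  reps <- function(x, eps = 1e-3) x * c(1 - eps, 1, 1 + eps)
  b <- lapply(setNames(c(10, 10, 10, 10), sprintf("g%d", 1:4)), reps)
  a <- list(g1 = reps(10), g2 = reps(20), g3 = reps(50), g4 = reps(8))
  lin <- differential_concentration(a, b, mode = "linear")
  expect_setequal(lin$up$gene, c("g2", "g3"))
  expect_setequal(lin$down$gene, "g4")
  l2 <- differential_concentration(a, b, mode = "log2")
  expect_equal(l2$up$gene, "g3")  # log2(5) ~ 2.32; log2(2) = 1 misses
  expect_equal(nrow(l2$down), 0)
  # label antisymmetry with reciprocal fold changes
  swapped <- differential_concentration(b, a, mode = "linear")
  expect_setequal(swapped$down$gene, lin$up$gene)
  expect_setequal(swapped$up$gene, lin$down$gene)
  m <- match(lin$up$gene, swapped$down$gene)
  expect_equal(swapped$down$fold_change[m], 1 / lin$up$fold_change)
  # identical groups produce empty lists
  none <- differential_concentration(b, b)
  expect_equal(nrow(none$up) + nrow(none$down), 0)
  expect_error(differential_concentration(list(x = 1:3), list(y = 1:3)),
               "shared")
})
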