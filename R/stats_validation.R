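#' @title Scores and statistical validation battery
#'
#' @description Measures used to validate the integrated atlas: a
#' coverage-penalized variability score, a location-specificity index on the
#' natural-log scale, pairwise correlation tables over shared proteins,
#' median-equality testing (Kruskal-Wallis with Conover post hoc and Holm
#' adjustment), a two-group battery of location, distribution and scale
#' tests with a median-to-spread effect size, a resampling procedure that
#' controls for unequal sample sizes, and threshold-based differential
#' concentration selection.
#'
#' @name stats_validation
NULL

#' Variability score of a protein's measurements
#'
#' Absolute coefficient of variation of the raw (not log-transformed) values
#' divided by the number of measurements: a dimensionless score that
#' penalizes both dispersion and sparse coverage, zero exactly when the CV is
#' zero. Undefined (NA, to be skipped) for fewer than two values or zero
#' mean.
#'
#' @param values numeric vector of measurements (linear scale)
#' @return scalar score, or `NA` when undefined
#' @export
variability_score <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) return(NA_real_)
  m <- mean(values)
  if (m == 0) return(NA_real_)
  abs(stats::sd(values) / m) / n
}

#' Specificity index of a protein for one location
#'
#' Difference in mean natural-log concentration between the target location
#' (a cell type or brain region) and all other locations pooled. Swapping
#' target and complement negates the index. Nonpositive concentrations are
#' dropped with a warning before taking logs.
#'
#' @param conc_by_location named list: location -> numeric vector of uM
#'   concentrations
#' @param target name of the target location
#' @return scalar index (dimensionless, natural-log units)
#' @export
specificity_index <- function(conc_by_location, target) {
  if (!(target %in% names(conc_by_location))) stop("target location absent")
  others <- conc_by_location[setdiff(names(conc_by_location), target)]
  if (length(others) == 0L) stop("complement is empty")
  clean <- function(x) {
    bad <- !is.finite(x) | x <= 0
    if (any(bad)) warning(sum(bad), " nonpositive concentration(s) dropped")
    x[!bad]
  }
  a <- clean(conc_by_location[[target]])
  b <- clean(unlist(others, use.names = FALSE))
  if (!length(a) || !length(b)) stop("no positive concentrations")
  mean(log(a)) - mean(log(b))
}

#' Proteins in the top quantile of overall concentration, per location
#'
#' The quantile threshold is computed over ALL concentrations (linear
#' interpolation of the empirical distribution); within each location the
#' genes strictly above the threshold are returned. With `q = 0.99` this
#' selects the top 1% of overall protein levels.
#'
#' @param entries data.frame with columns `canonical_gene`,
#'   `concentration_uM` and the grouping column
#' @param group_by grouping column name (`"cell_type"` or `"brain_region"`)
#' @param q quantile in (0, 1); `q = 0` degenerates to all genes
#' @return named list: location -> character vector of gene symbols
#' @export
top_percentile_proteins <- function(entries, group_by, q = 0.99) {
  stopifnot(group_by %in% names(entries), q >= 0, q < 1)
  thr <- stats::quantile(entries$concentration_uM, probs = q, names = FALSE,
                         type = 7)
  sel <- if (q == 0) rep(TRUE, nrow(entries)) else
    entries$concentration_uM > thr
  lapply(split(entries[sel, , drop = FALSE], entries[[group_by]][sel]),
         function(d) sort(unique(d$canonical_gene)))
}

#' Pairwise correlation of ln-concentrations across groups
#'
#' For every pair of groups (data sets, brain regions or cell types), the
#' Pearson correlation of natural-log concentrations is computed over the
#' proteins common to that pair only, independently per pair; the number of
#' common proteins is recorded. Multiple entries of one gene within a group
#' are averaged on the linear scale first. Pairs sharing fewer than 3
#' proteins get `NA`.
#'
#' @param entries data.frame with `canonical_gene`, `concentration_uM` and
#'   the grouping column
#' @param group_by grouping column name
#' @return list with square matrices `r` and `n_common`
#' @export
correlation_tables <- function(entries, group_by) {
  stopifnot(group_by %in% names(entries))
  groups <- split(entries, entries[[group_by]])
  if (length(groups) < 2L) stop("need at least 2 groups")
  per_gene <- lapply(groups, function(d)
    tapply(d$concentration_uM, d$canonical_gene, mean))
  k <- length(per_gene)
  r <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  n <- matrix(0L, k, k, dimnames = dimnames(r))
  diag(r) <- 1
  for (i in seq_len(k)) {
    n[i, i] <- length(per_gene[[i]])
    for (j in seq_len(k)) {
      if (j <= i) next
      common <- intersect(names(per_gene[[i]]), names(per_gene[[j]]))
      n[i, j] <- n[j, i] <- length(common)
      if (length(common) >= 3L) {
        r[i, j] <- r[j, i] <- stats::cor(log(per_gene[[i]][common]),
                                         log(per_gene[[j]][common]))
      }
    }
  }
  list(r = r, n_common = n)
}

# Conover-Iman all-pairs rank test after Kruskal-Wallis, with tie correction.
# t_ij = (Rbar_i - Rbar_j) / sqrt(S2 * (N-1-H)/(N-k) * (1/n_i + 1/n_j)),
# two-sided p from Student t with N - k degrees of freedom, where S2 is the
# variance of the pooled (tied) ranks and H the tie-corrected KW statistic.
conover_posthoc <- function(values, groups, kw_stat) {
  groups <- factor(groups)
  N <- length(values)
  k <- nlevels(groups)
  rk <- rank(values)
  s2 <- (sum(rk^2) - N * (N + 1)^2 / 4) / (N - 1)
  rbar <- tapply(rk, groups, mean)
  ng <- tabulate(groups)
  lev <- levels(groups)
  p <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  scale2 <- s2 * (N - 1 - kw_stat) / (N - k)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      tstat <- (rbar[i] - rbar[j]) /
        sqrt(scale2 * (1 / ng[i] + 1 / ng[j]))
      p[i, j] <- p[j, i] <- 2 * stats::pt(abs(tstat), df = N - k,
                                          lower.tail = FALSE)
    }
  }
  p
}

#' Median equality across multiple studies
#'
#' Kruskal-Wallis test over three or more groups of ln-concentrations; if it
#' rejects at `alpha`, the Conover all-pairs post hoc test is run and its
#' p-values are Holm-adjusted. With fewer than three groups a two-sample test
#' should be used instead.
#'
#' @param groups named list: study -> numeric vector of ln-concentrations,
#'   each of length >= 2
#' @param alpha rejection level for the omnibus test, default 0.05
#' @return list with `kw_statistic`, `kw_p`, `rejected`, and (when rejected)
#'   matrices `conover_p_raw` and `conover_p_holm`
#' @export
median_equality_battery <- function(groups, alpha = 0.05) {
  if (length(groups) < 3L)
    stop("fewer than 3 groups: use a two-sample test (two_group_battery)")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs at least 2 values")
  kw <- stats::kruskal.test(groups)
  out <- list(kw_statistic = unname(kw$statistic), kw_p = kw$p.value,
              rejected = kw$p.value < alpha,
              conover_p_raw = NULL, conover_p_holm = NULL)
  if (out$rejected) {
    values <- unlist(groups, use.names = FALSE)
    glab <- rep(names(groups), vapply(groups, length, 1L))
    praw <- conover_posthoc(values, glab, out$kw_statistic)
    phol <- praw
    upper <- upper.tri(praw)
    phol[upper] <- stats::p.adjust(praw[upper], method = "holm")
    phol[lower.tri(phol)] <- t(phol)[lower.tri(phol)]
    out$conover_p_raw <- praw
    out$conover_p_holm <- phol
  }
  out
}

# Tukey boxplot whiskers: furthest points within 1.5 IQR of the quartile.
boxplot_whiskers <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- x[x >= q[1] - 1.5 * iqr]
  hi <- x[x <= q[2] + 1.5 * iqr]
  c(lower = min(lo), upper = max(hi))
}

#' Two-group battery of location, distribution and scale tests
#'
#' Computes the distance-between-medians to overall-visible-spread ratio
#' (DBM/OVS, the spread being the span of the two groups' 1.5 x IQR boxplot
#' whiskers), the two-sided Wilcoxon-Mann-Whitney U and Kolmogorov-Smirnov
#' tests, and the Brown-Forsythe (median-centered Levene) and Fligner-Killeen
#' variance-homogeneity tests. A pure location shift moves DBM/OVS, MWU and
#' KS but leaves the scale tests null; a pure scale change does the reverse.
#'
#' @param a,b numeric vectors, each of length >= 5
#' @return list of class `battery_result` with `dbm_ovs`, `mwu_p`, `ks_p`,
#'   `brown_forsythe_p`, `fligner_killeen_p`
#' @export
two_group_battery <- function(a, b) {
  if (length(a) < 5L || length(b) < 5L)
    stop("each group needs at least 5 values")
  wa <- boxplot_whiskers(a)
  wb <- boxplot_whiskers(b)
  spread <- max(wa["upper"], wb["upper"]) - min(wa["lower"], wb["lower"])
  dbm_ovs <- if (spread > 0) {
    abs(stats::median(a) - stats::median(b)) / spread
  } else NA_real_

  mwu <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  ks_exact <- length(a) * length(b) <= 1e4 && !any(duplicated(c(a, b)))
  ks <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided",
                                        exact = ks_exact))
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  bf <- car::leveneTest(c(a, b), g, center = stats::median)
  fk <- stats::fligner.test(c(a, b), g)

  structure(list(dbm_ovs = unname(dbm_ovs),
                 mwu_p = mwu$p.value,
                 ks_p = ks$p.value,
                 brown_forsythe_p = bf[["Pr(>F)"]][1L],
                 fligner_killeen_p = fk$p.value),
            class = "battery_result")
}

#' Permutation calibration of the two-group battery
#'
#' Controls for unequal sample sizes by repeatedly drawing `n` values per
#' group (without replacement when the group is large enough, otherwise with
#' replacement) and recording each test's rejection rate at `alpha`. In
#' control mode both samples are drawn from the pooled data, so every test's
#' rejection rate should sit at its nominal level. Deterministic for a fixed
#' seed.
#'
#' @param a,b numeric vectors
#' @param n per-group sample size, default 100
#' @param reps number of resampling iterations, default 1000
#' @param seed integer seed
#' @param mode `"treatment"` (sample within each group) or `"control"`
#'   (sample both groups from the pooled data)
#' @param alpha rejection level, default 0.05
#' @return named numeric vector of rejection rates for `mwu`, `ks`,
#'   `brown_forsythe`, `fligner_killeen`
#' @export
permutation_battery <- function(a, b, n = 100L, reps = 1000L, seed = 1L,
                                mode = c("treatment", "control"),
                                alpha = 0.05) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  reps <- as.integer(reps)
  if (n < 5L || reps < 1L) stop("invalid n or reps")
  set.seed(seed)
  tests <- c("mwu", "ks", "brown_forsythe", "fligner_killeen")
  rejections <- stats::setNames(numeric(4L), tests)
  pool <- c(a, b)
  for (r in seq_len(reps)) {
    if (mode == "control") {
      if (length(pool) >= 2L * n) {
        idx <- sample.int(length(pool), 2L * n)
        xa <- pool[idx[seq_len(n)]]
        xb <- pool[idx[n + seq_len(n)]]
      } else {
        xa <- sample(pool, n, replace = TRUE)
        xb <- sample(pool, n, replace = TRUE)
      }
    } else {
      xa <- sample(a, n, replace = length(a) < n)
      xb <- sample(b, n, replace = length(b) < n)
    }
    res <- two_group_battery(xa, xb)
    p <- c(res$mwu_p, res$ks_p, res$brown_forsythe_p, res$fligner_killeen_p)
    rejections <- rejections + (p < alpha)
  }
  rejections / reps
}

#' Differential concentration selection between two groups
#'
#' Per-gene fold change `mean(A)/mean(B)` with a two-sided Welch t-test on
#' ln-concentrations. In `linear` mode genes with fold change >= 1.15 and
#' p < 0.05 are called up, fold change <= 0.87 and p < 0.05 down; in `log2`
#' mode the thresholds are log2 fold change >= 2 (up) and <= -2 (down).
#' Genes with fewer than two replicates in either group are skipped. Swapping
#' the groups maps the up list to the down list with reciprocal fold changes.
#'
#' @param group_a,group_b named lists: gene -> numeric vector of replicate
#'   concentrations (uM)
#' @param mode `"linear"` or `"log2"`
#' @param alpha significance level, default 0.05
#' @return list with data.frames `up` and `down` (columns `gene`,
#'   `fold_change`, `log2_fc`, `p`) and `table` (all tested genes)
#' @export
differential_concentration <- function(group_a, group_b,
                                       mode = c("linear", "log2"),
                                       alpha = 0.05) {
  mode <- match.arg(mode)
  common <- intersect(names(group_a), names(group_b))
  if (length(common) == 0L) stop("no genes shared between the groups")
  rows <- list()
  for (g in common) {
    xa <- group_a[[g]]
    xb <- group_b[[g]]
    if (length(xa) < 2L || length(xb) < 2L) next
    fc <- mean(xa) / mean(xb)
    p <- tryCatch(stats::t.test(log(xa), log(xb))$p.value,
                  error = function(e) NA_real_)
    rows[[g]] <- data.frame(gene = g, fold_change = fc, log2_fc = log2(fc),
                            p = p, stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), fold_change = numeric(),
               log2_fc = numeric(), p = numeric())
  rownames(tab) <- NULL
  sig <- !is.na(tab$p) & tab$p < alpha
  if (mode == "linear") {
    up <- sig & tab$fold_change >= 1.15
    down <- sig & tab$fold_change <= 0.87
  } else {
    up <- sig & tab$log2_fc >= 2
    down <- sig & tab$log2_fc <= -2
  }
  list(up = tab[up, , drop = FALSE], down = tab[down, , drop = FALSE],
       table = tab)
}
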