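one_study <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(gene = sprintf("G%03d", seq_len(n)),
             signal = stats::rlnorm(n, 10, 2),
             detectability = sample(1:40, n, replace = TRUE),
             mol_weight = stats::runif(n, 1e4, 3e5))
}

test_that("single-protein study hits the closed-form concentration", {
  for (sig in c(1, 42, 1e9)) {
    r <- estimate_study(data.frame(gene = "A", signal = sig,
                                   detectability = 7, mol_weight = 50000))
    expect_equal(r$table$concentration_uM, 4000)  # 200 g/L / 50 kg/mol
  }
})

test_that("total volume is protein-mass/concentration regardless of input", {
  for (seed in 1:3) {
    r <- estimate_study(one_study(50, seed))
    expect_equal(r$total_volume_L, 1e-12, tolerance = 1e-12)
  }
})

test_that("summed mass concentration equals the total protein density", {
  for (seed in 1:3) {
    r <- estimate_study(one_study(80, seed))
    mass <- sum(r$table$concentration_uM * 1e-6 * r$table$mol_weight)
    expect_equal(mass, 200, tolerance = 1e-9)
  }
})

test_that("global signal scaling cancels", {
  d <- one_study(40)
  r1 <- estimate_study(d)
  d$signal <- d$signal * 10
  r2 <- estimate_study(d)
  expect_equal(r2$table$concentration_uM, r1$table$concentration_uM)
  expect_equal(r2$table$copy_number, r1$table$copy_number)
})

test_that("equal proteins split the total concentration symmetrically", {
  r <- estimate_study(data.frame(gene = c("A", "B"), signal = c(6, 3),
                                 detectability = c(2, 1),
                                 mol_weight = c(8e4, 8e4)))
  expect_equal(r$table$concentration_uM, rep(200 / 8e4 * 1e6 / 2, 2))
})

test_that("zero-signal entries are dropped; all-zero studies error", {
  d <- one_study(10)
  d$signal[3] <- 0
  r <- estimate_study(d)
  expect_equal(nrow(r$table), 9)
  d$signal <- 0
  expect_error(estimate_study(d), "degenerate study")
})

test_that("reported units convert to uM", {
  expect_equal(convert_reported_units(2, "nM"), 0.002)
  expect_equal(convert_reported_units(1e-8, "mol_per_g_protein"), 2)
  expect_equal(convert_reported_units(0, "M"), 0)
  expect_equal(convert_reported_units(3, "uM"), 3)
  expect_error(convert_reported_units(1, "furlongs"), "furlongs")
})

ref_entries <- function() {
  data.frame(
    canonical_gene = c("HK1", "HK2", "HK3", "HK1", "OTHER"),
    concentration_uM = c(1, 2, 3, 100, 7),
    study_id = c("a", "a", "a", "mito", "a"),
    species = "mouse", condition = "healthy", age = "young",
    stringsAsFactors = FALSE)
}

test_that("reference median pools qualifying housekeeping entries", {
  e <- ref_entries()
  expect_equal(
    compute_reference_median(e, c("HK1", "HK2", "HK3"),
                             organelle_only_studies = "mito"),
    2)  # odd-count median of {1,2,3}; mitochondria-only study excluded
  two <- e[e$concentration_uM %in% c(1, 100), ]
  expect_equal(compute_reference_median(two, "HK1"), 50.5)  # even count
  old <- e
  old$age <- "old"
  expect_error(compute_reference_median(old, "HK1"), "no reference entries")
})

test_that("normalization equalizes housekeeping medians and is idempotent", {
  set.seed(3)
  hk <- sprintf("HK%d", 1:5)
  entries <- do.call(rbind, lapply(c("s1", "s2", "s3"), function(sid) {
    scale <- switch(sid, s1 = 1, s2 = 2, s3 = 0.25)
    data.frame(canonical_gene = c(hk, sprintf("G%d", 1:20)),
               concentration_uM = c(1:5, stats::rlnorm(20)) * scale,
               study_id = sid, stringsAsFactors = FALSE)
  }))
  ref <- 3
  norm1 <- normalize_to_reference(entries, hk, ref)
  for (sid in unique(norm1$study_id)) {
    hk_med <- median(norm1$concentration_uM[
      norm1$study_id == sid & norm1$canonical_gene %in% hk])
    expect_equal(hk_med, ref)
  }
  # a study at exactly the reference scale is untouched
  s1 <- norm1[norm1$study_id == "s1", ]
  expect_equal(s1$concentration_uM,
               entries$concentration_uM[entries$study_id == "s1"])
  # idempotence
  norm2 <- normalize_to_reference(norm1, hk, ref)
  expect_equal(norm2$concentration_uM, norm1$concentration_uM)
  # halving under a doubled housekeeping median
  s2_before <- entries$concentration_uM[entries$study_id == "s2"]
  s2_after <- norm1$concentration_uM[norm1$study_id == "s2"]
  expect_equal(s2_after, s2_before / 2)
})

test_that("studies without housekeeping coverage are rejected by name", {
  entries <- data.frame(canonical_gene = c("A", "B"),
                        concentration_uM = c(1, 2),
                        study_id = "lonely", stringsAsFactors = FALSE)
  expect_error(normalize_to_reference(entries, "HK1", 1), "lonely")
})
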