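test_that("proteome generation is seed-deterministic and well-formed", {
  p1 <- generate_proteome(100, seed = 3)
  p2 <- generate_proteome(100, seed = 3)
  expect_identical(p1, p2)
  expect_length(unique(p1$genes), 100)
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", p1$sequences)))
  # length/K-R parameters give at least one detectable peptide almost always
  expect_gt(mean(p1$theor_peptides >= 1), 0.9)
  expect_error(generate_proteome(5), ">= 10")
})

test_that("study simulation is deterministic and honours its rates", {
  p <- generate_proteome(150, seed = 4)
  s1 <- simulate_study(p, "s", "LFQ", batch_factor = 2, noise_cv = 0.2,
                       synonym_corruption_rate = 0.3, dropout_rate = 0.2,
                       seed = 10)
  s2 <- simulate_study(p, "s", "LFQ", batch_factor = 2, noise_cv = 0.2,
                       synonym_corruption_rate = 0.3, dropout_rate = 0.2,
                       seed = 10)
  expect_identical(s1$table, s2$table)
  expect_true(all(s1$table$value > 0))
  expect_true(nrow(s1$table) < 150)  # dropout happened
  expect_gt(length(s1$truth$corrupted), 0)
  expect_true(all(names(s1$truth$corrupted) %in% s1$table$gene))
  # housekeeping never fully dropped even at extreme dropout
  for (seed in 1:5) {
    s <- simulate_study(p, "x", "iBAQ", dropout_rate = 0.98, seed = seed)
    expect_gt(sum(p$housekeeping %in% s$table$gene), 0)
  }
  expect_error(simulate_study(p, "s", "LFQ", batch_factor = -1), "positive")
  expect_error(simulate_study(p, "s", "LFQ", noise_cv = 2), "rates")
})

test_that("a noiseless uncorrupted study is exactly identifiable", {
  p <- generate_proteome(60, seed = 6)
  s <- simulate_study(p, "clean", "LFQ", batch_factor = 7, noise_cv = 0,
                      seed = 2)
  genes <- s$table$gene
  inputs <- data.frame(gene = genes, signal = s$table$value,
                       detectability = p$theor_peptides[genes],
                       mol_weight = p$mol_weight[genes])
  est <- estimate_study(inputs)
  # concentrations proportional to true copies, batch factor fully cancelled
  ratio <- est$table$concentration_uM / p$true_copies[genes]
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-9)
})

test_that("corrupted labels are restored through the synonym graph", {
  p <- generate_proteome(300, seed = 8)
  studies <- lapply(1:5, function(i)
    simulate_study(p, paste0("s", i), "LFQ", noise_cv = 0.1,
                   synonym_corruption_rate = 0.2, seed = 20 + i))
  entry_names <- as.list(unlist(lapply(studies, function(s) s$table$gene)))
  graph <- build_synonym_graph(
    entry_names,
    strsplit(p$synonym_table$gene_names, "|", fixed = TRUE))
  truth_key <- canonical_labels(graph, p$genes)
  restored <- vapply(studies, function(s) {
    corrupted <- s$truth$corrupted
    mean(canonical_labels(graph, names(corrupted)) ==
           truth_key[match(corrupted, p$genes)])
  }, numeric(1))
  expect_true(all(restored >= 0.99))
})

test_that("metabolome records round-trip to the per-compartment truth", {
  m <- simulate_metabolome(10, seed = 12)
  back <- vapply(seq_len(nrow(m$records)), function(i)
    to_molar(m$records$value[i], m$records$unit[i],
             m$records$mol_weight[i], m$constants), numeric(1))
  truth <- m$truth_uM[cbind(tolower(m$records$name), m$records$compartment)]
  expect_equal(back, unname(truth), tolerance = 1e-9)
  expect_identical(simulate_metabolome(10, seed = 12)$records, m$records)
  expect_error(simulate_metabolome(3), ">= 5")
  expect_error(simulate_metabolome(8, compartments = "cytosol"),
               "unknown compartment")
})

test_that("noiseless compartment mixing matches simulated tissue ranks", {
  m <- simulate_metabolome(12, seed = 13)
  per_comp <- do.call(rbind, lapply(rownames(m$truth_uM), function(nm) {
    cid <- m$cid_table$cid[m$cid_table$name == nm]
    data.frame(cid = cid,
               compartment = c("neuron", "astrocyte", "blood",
                               "extracellular"),
               conc_uM = m$truth_uM[nm, c("neuron", "astrocyte", "blood",
                                          "extracellular")])
  }))
  mixed <- mix_tissue(per_comp)$predicted
  # zero-noise tissue "measurement" = the same convex combination
  fr <- tissue_composition()$fractions
  manual <- apply(m$truth_uM, 1, function(x)
    fr[["extracellular"]] * x[["extracellular"]] +
      fr[["vasculature"]] * x[["blood"]] +
      (fr[["neuron_soma"]] + fr[["neurites"]]) * x[["neuron"]] +
      fr[["glia"]] * x[["astrocyte"]])
  names(manual) <- as.character(
    m$cid_table$cid[match(names(manual), m$cid_table$name)])
  res <- compare_predicted_to_measured(mixed, manual)
  expect_equal(res$spearman_rho, 1)
  expect_equal(res$pearson_r, 1)
})
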