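test_that("protein generation is seeded and compositionally uniform", {
  expect_identical(generate_protein(100, 1)$sequence,
                   generate_protein(100, 1)$sequence)
  expect_false(identical(generate_protein(100, 1)$sequence,
                         generate_protein(100, 2)$sequence))
  expect_equal(protein_length(generate_protein(100, 3)), 100L)
  big <- generate_protein(100000, 4)
  freq <- table(strsplit(big$sequence, "")[[1]]) / 100000
  se <- sqrt(0.05 * 0.95 / 100000)
  expect_true(all(abs(freq - 0.05) < 3 * se + 1e-9))
})

test_that("simulated identifications contain both products at each planted site", {
  prot <- generate_protein(150, seed = 71)
  sim <- simulate_shedding_identifications(prot, c(50L, 90L), decoy_rate = 0,
                                           seed = 72)
  for (s in c(50L, 90L)) {
    expect_true(any(sim$peptides$end == s), info = paste("n-product at", s))
    expect_true(any(sim$peptides$start == s + 1L), info = paste("c-product at", s))
  }
  expect_false(any(sim$peptides$is_decoy))
  expect_equal(sim$truth$planted_sites, c(50L, 90L))
})

test_that("decoys have non-canonical termini away from planted bonds", {
  prot <- generate_protein(150, seed = 73)
  proteases <- default_proteases()
  sim <- simulate_shedding_identifications(prot, 64L, decoy_rate = 0.1,
                                           proteases = proteases, seed = 74)
  decoys <- sim$peptides[sim$peptides$is_decoy, ]
  expect_gt(nrow(decoys), 0L)
  for (i in seq_len(nrow(decoys))) {
    expect_false(decoys$end[i] == 64L || decoys$start[i] - 1L == 64L)
    lab <- classify_termini(decoys[i, ], prot, proteases[[decoys$protease[i]]])
    expect_true(all(lab == "non_canonical"))
  }
})

test_that("noise-free spectrum pairs are identical; series dropout removes a series", {
  pair <- simulate_spectrum_pair("EVLQRPASIME", noise_sd = 0, dropout = 0,
                                 n_background = 0, seed = 75)
  m <- match_fragment_sets(pair$acquired, pair$predicted, "EVLQRPASIME")
  expect_equal(spectrum_contrast_angle(m$acquired, m$predicted), 1,
               tolerance = 1e-12)
  pair_b <- simulate_spectrum_pair("EVLQRPASIME", noise_sd = 0,
                                   dropout = c(b = 1, y = 0),
                                   n_background = 0, seed = 76)
  mb <- match_fragment_sets(pair_b$acquired, pair_b$predicted, "EVLQRPASIME")
  expect_true(all(mb$series == "y"))
})

test_that("SCA degrades in expectation as spectral noise rises", {
  mean_sca <- sapply(c(0, 0.3, 0.8, 1.5), function(ns) {
    vals <- sapply(1:40, function(r) {
      pair <- simulate_spectrum_pair("EVLQRPASIME", noise_sd = ns, dropout = 0,
                                     n_background = 0, seed = 2000 + r)
      m <- match_fragment_sets(pair$acquired, pair$predicted, "EVLQRPASIME")
      spectrum_contrast_angle(select_top_k(m, 8)$acquired,
                              select_top_k(m, 8)$predicted)
    })
    mean(vals)
  })
  expect_true(all(diff(mean_sca) < 0))
})

test_that("proteome simulation embeds MNAR missingness and group effects", {
  sim <- simulate_proteome(n_proteins = 500, n_per_group = 3, effect_size = 4,
                           seed = 81)
  # missingness increases as true intensity decreases
  miss_rate <- rowMeans(is.na(sim$matrix))
  true_mean <- rowMeans(sim$full_matrix)
  ct <- cor.test(true_mean, miss_rate, method = "spearman", exact = FALSE)
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  # affected proteins are shifted between groups in the full matrix
  d <- rowMeans(sim$full_matrix[, sim$groups == "A"]) -
       rowMeans(sim$full_matrix[, sim$groups == "B"])
  expect_gt(mean(d[sim$affected]), 3)
  expect_lt(abs(mean(d[!sim$affected])), 0.2)
  # pure function of (config, seed)
  sim2 <- simulate_proteome(n_proteins = 500, n_per_group = 3, effect_size = 4,
                            seed = 81)
  expect_identical(sim$matrix, sim2$matrix)
})

test_that("strong effects survive imputation and the printed volcano cuts", {
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    sim <- simulate_proteome(n_proteins = 300, n_per_group = 3, effect_size = 4,
                             frac_affected = 0.1, seed = 900 + s)
    imp <- impute_missing(sim$matrix, seed = 900 + s)
    res <- classify_volcano(differential_test(imp$matrix, sim$groups))
    hits <- hits + sum(res$class == "up_A" & sim$affected)
    total <- total + sum(sim$affected)
  }
  expect_gte(hits / total, 0.9)
})

test_that("plate and FRET generators expose recoverable ground truth", {
  sim0 <- simulate_plate(c(ctrl = 0.15, null = 0.15), n_wells = 6,
                         noise_sd = 2, seed = 91)
  res0 <- shedding_ratio(sim0$plate, "ctrl", sim0$background)
  expect_equal(res0$normalized_ratio[res0$condition == "null"], 1,
               tolerance = 0.1)
  ft <- simulate_fret_trace(noise_sd = 0, seed = 92)
  out <- fret_normalize(ft$trace, ft$ligand_index, ft$stimulus_index,
                        ft$bleed_through, ft$background)
  expect_lt(max(abs(out$response - ft$truth$response_percent)), 1e-6)
})
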