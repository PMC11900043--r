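test_that("config validation enforces the kernel and count invariants", {
  expect_error(sim_config(decay_amplitude = 0.8, baseline_corr = 0.3),
               "must not exceed 1")
  expect_error(sim_config(decay_length = 0), "decay_length")
  expect_error(sim_config(genes_per_chromosome = 0), "counts")
})

test_that("simulated genomes are ordered, non-overlapping and deterministic", {
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 7, seed = 42L)
  ann <- simulate_genome(cfg)
  genes <- ann[ann$feature == "gene", ]
  expect_equal(nrow(genes), 7)
  expect_true(all(diff(genes$start) > 0))
  expect_true(all(genes$start[-1] > genes$end[-nrow(genes)]))
  expect_equal(sum(ann$feature == "centromere"), 1)
  expect_identical(ann, simulate_genome(cfg))

  # degenerate single-gene chromosome: empty neighborhood, no error
  solo <- simulate_genome(sim_config(n_chromosomes = 1,
                                     genes_per_chromosome = 1, seed = 1L))
  nb <- neighborhood(solo, solo$gene_id[solo$feature == "gene"][1], k = 3)
  expect_equal(nrow(nb), 0)
})

test_that("simulated expression reproduces the decay kernel empirically", {
  # adjacent genes 1000 bp apart, a0 = 0.8, c0 = 0, lambda0 = 5000:
  # closed-form pair correlation is 0.8 * exp(-1000/5000)
  ann <- two_gene_annotation(gap_bp = 1000)
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 2,
                    decay_amplitude = 0.8, baseline_corr = 0,
                    decay_length = 5000, n_blocks = 1,
                    samples_per_block = 2000, block_shift_sd = 0, seed = 8L)
  expr <- simulate_expression(ann, cfg)
  r <- pcc(expr$values["gA", ], expr$values["gB", ])
  expect_equal(r, 0.8 * exp(-1000 / 5000), tolerance = 0.05 / 0.65)
  expect_lt(abs(r - 0.8 * exp(-1000 / 5000)), 0.05)

  # lambda -> 0: decay term vanishes, neighbor correlation ~ c0
  cfg0 <- sim_config(n_chromosomes = 1, genes_per_chromosome = 2,
                     decay_amplitude = 0.8, baseline_corr = 0.1,
                     decay_length = 1, n_blocks = 1,
                     samples_per_block = 500, block_shift_sd = 0, seed = 9L)
  expr0 <- simulate_expression(ann, cfg0)
  r0 <- pcc(expr0$values["gA", ], expr0$values["gB", ])
  expect_lt(abs(r0 - 0.1), 0.1)

  # determinism
  expect_identical(simulate_expression(ann, cfg)$values, expr$values)
})

test_that("simulated qPCR tables recover the generating fold change", {
  folds <- c(WT = 1, quad = 4)
  ct <- simulate_qpcr(folds, n_replicates = 8, seed = 21L, ct_sd = 0.1)
  expect_true(all(ct$ct > 0))
  est <- ddct(ct, target = "YCP4", calibrator = "WT")
  expect_lt(abs(est$fold[est$strain == "quad"] - 4) / 4, 0.15)

  # null folds center on ddct = 0 (averaged over replicates of tables)
  dd <- vapply(1:20, function(i) {
    tab <- simulate_qpcr(c(WT = 1, s2 = 1), n_replicates = 4, seed = 100L + i)
    est <- ddct(tab, target = "YCP4", calibrator = "WT")
    est$ddct[est$strain == "s2"]
  }, numeric(1))
  expect_lt(abs(mean(dd)), 0.05)
  expect_identical(ct, simulate_qpcr(folds, n_replicates = 8, seed = 21L,
                                     ct_sd = 0.1))
})

test_that("simulated growth grids honour bounds, monotonicity and fitness", {
  g <- simulate_growth(c(WT = 1, half = 0.5, dead = 0), n_dilutions = 5,
                       n_replicates = 20, seed = 3L)
  expect_true(all(g$score >= 0 & g$score <= 1))
  # mean score non-increasing with dilution step in the control grids
  prof <- tapply(g$score[g$condition == "30C"],
                 g$dilution[g$condition == "30C"], mean)
  expect_true(all(diff(prof) <= 0))
  rg <- relative_growth(g)
  expect_lt(abs(rg$relative_growth[rg$strain == "WT"] - 1), 0.1)
  expect_lt(abs(rg$relative_growth[rg$strain == "half"] - 0.5), 0.1)
  expect_identical(rg$relative_growth[rg$strain == "dead"], 0)
  expect_true(all(g$score[g$condition == "40C" & g$strain == "dead"] == 0))
  expect_identical(g, simulate_growth(c(WT = 1, half = 0.5, dead = 0),
                                      n_dilutions = 5, n_replicates = 20,
                                      seed = 3L))
})
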