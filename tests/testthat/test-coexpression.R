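test_that("pcc matches the product-moment definition and its invariances", {
  expect_identical(pcc(1:5, 1:5), 1)
  expect_equal(pcc(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(pcc(c(1, 2, 3, 4), c(1, 3, 2, 4)),
               pcc_oracle(c(1, 2, 3, 4), c(1, 3, 2, 4)))
  set.seed(5)
  for (i in 1:50) {
    x <- rnorm(7); y <- rnorm(7)
    expect_equal(pcc(x, y), pcc_oracle(x, y), tolerance = 1e-12)
    # scale/shift invariance
    expect_equal(pcc(x, 2 * y + 3), pcc(x, y), tolerance = 1e-12)
    expect_equal(pcc(x, y), pcc(y, x))
  }
})

test_that("pcc returns an undefined signal, never 0, on degenerate input", {
  expect_identical(pcc(rep(1, 5), rnorm(5)), NA_real_)
  expect_identical(pcc(c(1, 2, NA, NA, NA), c(1, 2, NA, NA, NA)), NA_real_)
  # pairwise deletion: only complete pairs enter
  x <- c(1, 2, 3, 4, NA)
  y <- c(1, 3, 2, NA, 5)
  expect_equal(pcc(x, y), pcc_oracle(c(1, 2, 3), c(1, 3, 2)))
})

test_that("expression round-trip and manifest validation behave", {
  cfg <- quick_config()
  expr <- simulate_expression(simulate_genome(cfg), cfg)
  mp <- withr::local_tempfile(fileext = ".tsv")
  fp <- withr::local_tempfile(fileext = ".tsv")
  write_expression(expr, mp, fp)
  back <- suppressMessages(load_expression(mp, fp))
  expect_equal(back$values, expr$values)
  expect_equal(back$manifest, expr$manifest)

  short <- expr$manifest[-1, ]
  expect_error(expression_matrix(expr$values, short),
               expr$manifest$sample_id[1])
})

test_that("locus profiles follow the generating kernel", {
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 15,
                    decay_amplitude = 0.8, baseline_corr = 0,
                    decay_length = 5000, n_blocks = 1,
                    samples_per_block = 1500, block_shift_sd = 0, seed = 17L)
  ann <- simulate_genome(cfg)
  expr <- simulate_expression(ann, cfg)
  genes <- ann$gene_id[ann$feature == "gene"]
  nb <- neighborhood(ann, genes[8], k = 6)
  prof <- locus_profile(expr, nb)
  # kernel is monotone in |distance|: rank correlation must be negative
  expect_lt(cor(abs(prof$signed_distance), prof$pcc, method = "spearman"), 0)

  # duplicated focal as neighbors: self-correlation rows are exactly 1
  dup <- expr
  dup$values[nb$neighbor[1], ] <- dup$values[genes[8], ]
  prof2 <- locus_profile(dup, nb)
  expect_equal(prof2$pcc[prof2$neighbor == nb$neighbor[1]], 1)

  # independent noise: correlations near zero
  noise_vals <- matrix(rnorm(5 * 1000), nrow = 5,
                       dimnames = list(c("f", paste0("n", 1:4)),
                                       paste0("s", 1:1000)))
  noise_expr <- expression_matrix(
    noise_vals, tibble::tibble(sample_id = paste0("s", 1:1000),
                               block_name = "b1"))
  nb0 <- tibble::tibble(focal = "f", neighbor = paste0("n", 1:4),
                        offset = c(-2L, -1L, 1L, 2L),
                        signed_distance = c(-2000, -1000, 1000, 2000),
                        direction = "left", is_essential = FALSE)
  prof0 <- locus_profile(noise_expr, nb0)
  expect_true(all(abs(prof0$pcc) < 0.1))

  expect_error(locus_profile(expr, dplyr::mutate(nb, focal = "absent")),
               "focal gene absent")
})

test_that("locus averages are plain means bounded by their entries", {
  prof <- tibble::tibble(pcc = c(0.8, 0))
  expect_equal(locus_average_pcc(prof), 0.4)
  prof2 <- tibble::tibble(pcc = c(0.2, NA, 0.6, -0.1))
  avg <- locus_average_pcc(prof2)
  expect_equal(avg, mean(c(0.2, 0.6, -0.1)))
  expect_gte(avg, min(prof2$pcc, na.rm = TRUE))
  expect_lte(avg, max(prof2$pcc, na.rm = TRUE))
  expect_warning(expect_identical(
    locus_average_pcc(tibble::tibble(pcc = NA_real_)), NA_real_))
})

test_that("condition heatmaps keep genomic rows and cluster columns", {
  set.seed(33)
  blocks <- c("heat", "peroxide", "diamide", "osmotic")
  prof <- tidyr::expand_grid(
    focal = "f", block = blocks,
    tibble::tibble(neighbor = c("a", "b", "c", "d"),
                   offset = c(-2L, -1L, 1L, 2L),
                   signed_distance = c(-3000, -1500, 1200, 2600))
  )
  prof$pcc <- runif(nrow(prof), -0.4, 0.9)
  # two identical condition columns must merge first
  prof$pcc[prof$block == "peroxide"] <- prof$pcc[prof$block == "heat"]
  hm <- condition_heatmap(prof)
  expect_equal(rownames(hm$matrix), c("a", "b", "f", "c", "d"))
  expect_true(all(hm$matrix["f", ] == 1))
  expect_setequal(hm$hclust$labels[-hm$hclust$merge[1, ]],
                  c("heat", "peroxide"))
  # strong-cell annotation at |pcc| > 0.5
  expect_identical(hm$strong, !is.na(hm$matrix) & abs(hm$matrix) > 0.5)

  # permuting input row order leaves the dendrogram topology unchanged
  hm2 <- condition_heatmap(prof[sample(nrow(prof)), ])
  coph <- function(h) {
    m <- as.matrix(stats::cophenetic(h$hclust))
    m[order(rownames(m)), order(colnames(m))]
  }
  expect_equal(coph(hm), coph(hm2))
  expect_error(condition_heatmap(prof[prof$block == "heat", ]), ">= 2 blocks")
})
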