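toy_orders <- function() {
  ref <- tibble::tibble(species = "ref", position = 1:5,
                        gene_id = paste0("r", 1:5),
                        family = c("F1", "F2", "F3", "F4", "F5"))
  same <- dplyr::mutate(ref, species = "twin", gene_id = paste0("t", 1:5))
  dplyr::bind_rows(ref, same)
}

test_that("a species identical to the reference is fully conserved", {
  st <- align_orders(toy_orders(), anchor = "F3")
  expect_true(all(st$cells$status == "present"))
  expect_equal(nrow(st$insertions), 0)
  summ <- conservation_summary(st)
  expect_true(all(summ$n_lost == 0))
  expect_true(all(summ$n_present == 2))
})

test_that("an extra gene between anchor and +1 is one insertion of size 1", {
  orders <- dplyr::bind_rows(
    toy_orders(),
    tibble::tibble(species = "ins", position = 1:6,
                   gene_id = paste0("i", 1:6),
                   family = c("F1", "F2", "F3", "X_private", "F4", "F5"))
  )
  st <- align_orders(orders, anchor = "F3")
  ins <- st$insertions[st$insertions$species == "ins", ]
  expect_equal(nrow(ins), 1)
  expect_identical(ins$after_family, "F3")
  expect_identical(as.integer(ins$n_inserted), 1L)
})

test_that("a species lacking the anchor still gets calls on other columns", {
  orders <- dplyr::bind_rows(
    toy_orders(),
    tibble::tibble(species = "noanchor", position = 1:4,
                   gene_id = paste0("n", 1:4),
                   family = c("F1", "F2", "F4", "F5"))
  )
  st <- align_orders(orders, anchor = "F3")
  cells <- st$cells[st$cells$species == "noanchor", ]
  expect_identical(cells$status[cells$family == "F3"], "lost")
  expect_true(all(cells$status[cells$family != "F3"] == "present"))
})

test_that("counts partition species and calls are orientation-agnostic", {
  orders <- dplyr::bind_rows(
    toy_orders(),
    tibble::tibble(species = "flipped", position = 1:5,
                   gene_id = paste0("f", 5:1),
                   family = c("F5", "F4", "F3", "F2", "F1"))
  )
  st <- align_orders(orders, anchor = "F3")
  summ <- conservation_summary(st)
  expect_true(all(summ$n_present + summ$n_lost == 3))
  flipped <- st$cells[st$cells$species == "flipped", ]
  expect_true(all(flipped$status == "present"))
})

test_that("alignment is idempotent on the reference", {
  st1 <- align_orders(toy_orders(), anchor = "F3")
  ref_again <- st1$cells[st1$cells$species == "ref", ]
  back <- tibble::tibble(species = "ref", position = ref_again$position,
                         gene_id = ref_again$gene_id,
                         family = ref_again$family)
  st2 <- align_orders(back, anchor = "F3")
  expect_equal(st2$columns, st1$columns)
  expect_true(all(st2$cells$status == "present"))
})

test_that("the packaged YCP4 panel reproduces the conservation narrative", {
  st <- align_orders(ycp4_synteny_panel(), anchor = "YCP4")
  summ <- conservation_summary(st)
  ycp4_lost <- st$cells$species[st$cells$family == "YCP4" &
                                  st$cells$status == "lost"]
  expect_setequal(ycp4_lost, c("T_blattae", "E_gossypii"))
  expect_equal(summ$n_lost[summ$family == "CIT2"], 0)
  # the distal anchors of the opposite arm are retained everywhere
  for (fam in c("RER1", "PGS1", "LBD16")) {
    expect_equal(summ$n_lost[summ$family == fam], 0)
  }
  expect_gt(sum(summ$n_inserted_adjacent), 0)
})

test_that("cross-species profiles reuse the locus machinery per species", {
  cfg <- quick_config()
  ann <- simulate_genome(cfg)
  expr <- simulate_expression(ann, cfg)
  genes <- ann$gene_id[ann$feature == "gene"]
  nb <- neighborhood(ann, genes[5], k = 2)

  prof <- cross_species_profiles(list(sp1 = expr, sp2 = expr), nb)
  p1 <- prof[prof$species == "sp1", -1]
  p2 <- prof[prof$species == "sp2", -1]
  expect_equal(p1, p2)

  # a species missing one neighbor keeps the row with pcc = NA
  drop_gene <- nb$neighbor[1]
  expr2 <- expression_matrix(
    expr$values[setdiff(rownames(expr$values), drop_gene), ],
    expr$manifest)
  prof2 <- cross_species_profiles(list(sp1 = expr, sp2 = expr2), nb)
  row2 <- prof2[prof2$species == "sp2" & prof2$neighbor == drop_gene, ]
  expect_true(is.na(row2$pcc))
  others <- prof2[prof2$species == "sp2" & prof2$neighbor != drop_gene, ]
  expect_equal(others$pcc,
               prof2$pcc[prof2$species == "sp1" &
                           prof2$neighbor != drop_gene])
})
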