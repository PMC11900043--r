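test_that("GFF3 round-trip preserves a simulated annotation", {
  ann <- simulate_genome(quick_config())
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(ann, path)
  back <- load_annotation(path)
  expect_equal(as.data.frame(back), as.data.frame(ann))
})

test_that("GFF3 loader validates coordinates and ignores unknown types", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t100\t900\t.\t+\t.\tID=gA",
    "chr1\tx\tgene\t1500\t2200\t.\t-\t.\tID=gB",
    "chr1\tx\tgene\t3000\t3900\t.\t+\t.\tID=gC"
  ), path)
  ann <- load_annotation(path)
  expect_equal(ann$gene_id, c("gA", "gB", "gC"))
  expect_true(all(diff(ann$start) > 0))

  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t100\t900\t.\t+\t.\tID=gA",
    "chr1\tx\tgene\t5000\t2200\t.\t-\t.\tID=gB"
  ), bad)
  expect_error(load_annotation(bad), "line\\(s\\): 3")

  odd <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t100\t900\t.\t+\t.\tID=gA",
    "chr1\tx\tgene\t1000\t1900\t.\t+\t.\tID=gB",
    "chr1\tx\tCDS\t100\t400\t.\t+\t.\tID=gA.cds",
    "chr1\tx\tmRNA\t100\t900\t.\t+\t.\tID=gA.t1"
  ), odd)
  expect_message(ann2 <- load_annotation(odd), "2 record\\(s\\).*ignored")
  expect_equal(nrow(ann2), 2)
})

test_that("neighborhood extraction reproduces the packaged flanking pairs", {
  ann <- scer_gene_order()
  expected <- list(
    AQY1 = c(tel = "HPA1", cen = "QCR2"),
    ATH1 = c(tel = "YPR027C", cen = "CCL1"),
    CAR1 = c(tel = "PEX25", cen = "GDE1"),
    POG1 = c(tel = "SIM1", cen = "QDR2"),
    PUT1 = c(tel = "DPH6", cen = "RRN5"),
    YCP4 = c(tel = "CIT2", cen = "MRPL32")
  )
  for (g in names(expected)) {
    nb <- neighborhood(ann, g, k = 1)
    expect_equal(nrow(nb), 2)
    expect_identical(nb$neighbor[nb$direction == "telomeric"],
                     unname(expected[[g]]["tel"]))
    expect_identical(nb$neighbor[nb$direction == "centromeric"],
                     unname(expected[[g]]["cen"]))
  }
  expect_true(neighborhood(ann, "PUT1", 1)$is_essential[
    neighborhood(ann, "PUT1", 1)$neighbor == "RRN5"])
  expect_true(neighborhood(ann, "ATH1", 1)$is_essential[
    neighborhood(ann, "ATH1", 1)$neighbor == "CCL1"])
})

test_that("neighborhoods truncate at chromosome ends and reject unknown genes", {
  ann <- simulate_genome(quick_config())
  genes <- ann$gene_id[ann$feature == "gene"]
  nb <- neighborhood(ann, genes[1], k = 3)
  expect_true(all(nb$offset > 0))
  expect_lte(nrow(nb), 3)
  expect_error(neighborhood(ann, "no_such_gene", k = 1), "not found")
})

test_that("signed distances are antisymmetric and strand-agnostic", {
  ann <- simulate_genome(quick_config())
  genes <- ann$gene_id[ann$feature == "gene"]
  nb_a <- neighborhood(ann, genes[4], k = 2)
  nb_b <- neighborhood(ann, genes[5], k = 2)
  d_ab <- nb_a$signed_distance[nb_a$neighbor == genes[5]]
  d_ba <- nb_b$signed_distance[nb_b$neighbor == genes[4]]
  expect_equal(d_ab, -d_ba)

  flipped <- ann
  flipped$strand <- ifelse(flipped$strand == "+", "-", "+")
  nb_f <- neighborhood(flipped, genes[4], k = 2)
  expect_equal(nb_f$neighbor, nb_a$neighbor)
  expect_equal(nb_f$signed_distance, nb_a$signed_distance)
})

test_that("direction labels fall back to left/right without a centromere", {
  ann <- simulate_genome(quick_config())
  no_cen <- ann[ann$feature != "centromere", ]
  genes <- no_cen$gene_id[no_cen$feature == "gene"]
  nb <- neighborhood(no_cen, genes[4], k = 1)
  expect_setequal(nb$direction, c("left", "right"))
})
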