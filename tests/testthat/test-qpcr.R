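make_ct <- function(strains, target_ct, ref_ct = 17, n = 3,
                    target = "YCP4", reference = "ACT1") {
  dplyr::bind_rows(lapply(seq_along(strains), function(i) {
    tibble::tibble(
      strain = strains[i],
      gene = rep(c(target, reference), each = n),
      replicate = rep(seq_len(n), 2),
      ct = c(rep(target_ct[i], n), rep(ref_ct, n)),
      melt_ok = TRUE
    )
  }))
}

test_that("ddct closed forms hold exactly", {
  # all Ct equal across strains and genes -> fold 1 everywhere
  flat <- make_ct(c("WT", "a", "b"), target_ct = c(20, 20, 20), ref_ct = 20)
  est <- ddct(flat, target = "YCP4", calibrator = "WT")
  expect_true(all(est$fold == 1))
  expect_identical(est$fold[est$strain == "WT"], 1)

  # target lower by exactly 1 cycle -> fold 2
  one <- make_ct(c("WT", "m"), target_ct = c(24, 23))
  est1 <- ddct(one, target = "YCP4", calibrator = "WT")
  expect_equal(est1$fold[est1$strain == "m"], 2)

  # ddct = -2 -> fold 4
  two <- make_ct(c("WT", "m"), target_ct = c(24, 22))
  est2 <- ddct(two, target = "YCP4", calibrator = "WT")
  expect_equal(est2$ddct[est2$strain == "m"], -2)
  expect_equal(est2$fold[est2$strain == "m"], 4)
})

test_that("ddct is invariant to adding a constant to every Ct", {
  ct <- simulate_qpcr(c(WT = 1, m = 2.5), n_replicates = 4, seed = 12L)
  base <- ddct(ct, target = "YCP4", calibrator = "WT")
  shifted <- dplyr::mutate(ct, ct = ct + 3.7)
  est <- ddct(shifted, target = "YCP4", calibrator = "WT")
  expect_equal(est$fold, base$fold)
  expect_equal(est$ddct, base$ddct)
})

test_that("melt filtering and missing references are enforced", {
  ct <- make_ct(c("WT", "m"), target_ct = c(24, 23))
  ct$melt_ok[ct$strain == "m" & ct$gene == "YCP4"] <- FALSE
  expect_warning(est <- ddct(ct, target = "YCP4", calibrator = "WT"),
                 "dropped")
  expect_false("m" %in% est$strain)

  no_ref <- dplyr::filter(make_ct(c("WT", "m"), c(24, 23)),
                          !(strain == "m" & gene == "ACT1"))
  expect_error(ddct(no_ref, target = "YCP4", calibrator = "WT"),
               "reference-gene")
  expect_error(ddct(dplyr::mutate(make_ct("WT", 24), ct = -ct),
                    target = "YCP4", calibrator = "WT"), "positive")
})

test_that("expression comparison is exact on identical replicates and
           recovers simulated folds", {
  ct <- make_ct(c("WT", "m"), target_ct = c(24, 24))
  ct$ct <- ct$ct + rep(c(0.1, -0.1, 0), 4)  # same pattern in both strains
  res <- compare_expression(ct, "m", "WT", target = "YCP4")
  expect_identical(res$p_value, 1)
  expect_identical(res$t, 0)
  expect_equal(res$fold_ratio, 1)

  sim <- simulate_qpcr(c(WT = 1, up = 4), n_replicates = 8, seed = 31L,
                       ct_sd = 0.1)
  res2 <- compare_expression(sim, "up", "WT", target = "YCP4")
  expect_lt(res2$p_value, 0.05)
  expect_lt(abs(res2$fold_ratio - 4) / 4, 0.2)

  # estimated fold converges to truth as replicates grow
  big <- simulate_qpcr(c(WT = 1, up = 3), n_replicates = 64, seed = 32L,
                       ct_sd = 0.1)
  est <- ddct(big, target = "YCP4", calibrator = "WT")
  expect_lt(abs(est$fold[est$strain == "up"] - 3) / 3, 0.05)
})
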