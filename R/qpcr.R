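#' Relative expression by the 2^-ddCt method
#'
#' Classic relative quantification for qPCR: per strain,
#' \eqn{\Delta Ct = \overline{Ct}_{target} - \overline{Ct}_{reference}}
#' (replicates averaged on the Ct scale),
#' \eqn{\Delta\Delta Ct = \Delta Ct_{strain} - \Delta Ct_{calibrator}}, and
#' fold change \eqn{2^{-\Delta\Delta Ct}}, assuming the canonical
#' amplification efficiency of 2 per cycle. An efficiency-corrected variant
#' (fold \eqn{= E^{-\Delta\Delta Ct}}) is available through `efficiency`.
#'
#' Reactions failing the melt-curve check (`melt_ok = FALSE`, i.e. more
#' than one amplicon) are excluded first. The SEM of the fold change is
#' propagated from replicate Ct variability by the delta method, including
#' the calibrator's own uncertainty.
#'
#' @param ct_table a tibble with columns `strain`, `gene`, `replicate`,
#'   `ct`, and optionally `melt_ok` (default all `TRUE`).
#' @param target target gene id.
#' @param reference reference (normalizer) gene id, default `"ACT1"`.
#' @param calibrator calibrator strain (fold = 1 by construction).
#' @param efficiency amplification efficiency per cycle (default 2).
#' @param min_replicates minimum usable replicates per (strain, gene).
#' @return A tibble: `strain`, `gene`, `delta_ct`, `ddct`, `fold`,
#'   `sem_fold`, `n_target`, `n_reference`.
#' @export
#' @examples
#' ct <- simulate_qpcr(c(WT = 1, mut = 4), n_replicates = 4, seed = 7)
#' ddct(ct, target = "YCP4", calibrator = "WT")
ddct <- function(ct_table, target, reference = "ACT1", calibrator,
                 efficiency = 2, min_replicates = 2) {
  ct_table <- tibble::as_tibble(ct_table)
  if (!"melt_ok" %in% names(ct_table)) ct_table$melt_ok <- TRUE
  if (any(ct_table$ct <= 0, na.rm = TRUE)) {
    abort_locusecho("Ct values must be positive")
  }
  ok <- dplyr::filter(ct_table, .data$melt_ok,
                      .data$gene %in% c(target, reference))
  per <- ok |>
    dplyr::group_by(.data$strain, .data$gene) |>
    dplyr::summarise(mean_ct = mean(.data$ct),
                     se_ct = stats::sd(.data$ct) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  strains <- unique(ct_table$strain)
  no_ref <- setdiff(strains, per$strain[per$gene == reference & per$n >= 1])
  if (length(no_ref) > 0) {
    abort_locusecho(paste0("no usable reference-gene (", reference,
                           ") reactions for strain(s): ",
                           paste(no_ref, collapse = ", ")))
  }
  dropped <- setdiff(strains, per$strain[per$gene == target &
                                           per$n >= min_replicates])
  if (length(dropped) > 0) {
    warning("strain(s) dropped (fewer than ", min_replicates,
            " usable target replicates): ", paste(dropped, collapse = ", "))
  }
  keep <- setdiff(strains, dropped)
  if (!calibrator %in% keep) {
    abort_locusecho(paste0("calibrator strain unusable or absent: ", calibrator))
  }
  wide <- per |>
    dplyr::filter(.data$strain %in% keep) |>
    tidyr::pivot_wider(names_from = "gene",
                       values_from = c("mean_ct", "se_ct", "n"))
  dct <- wide[[paste0("mean_ct_", target)]] - wide[[paste0("mean_ct_", reference)]]
  se_dct <- sqrt(wide[[paste0("se_ct_", target)]]^2 +
                   wide[[paste0("se_ct_", reference)]]^2)
  cal_i <- which(wide$strain == calibrator)
  ddct_v <- dct - dct[cal_i]
  se_ddct <- sqrt(se_dct^2 + ifelse(seq_along(dct) == cal_i, 0, se_dct[cal_i]^2))
  fold <- efficiency^(-ddct_v)
  tibble::tibble(
    strain = wide$strain, gene = target,
    delta_ct = dct, ddct = ddct_v, fold = fold,
    sem_fold = fold * log(efficiency) * se_ddct,
    n_target = wide[[paste0("n_", target)]],
    n_reference = wide[[paste0("n_", reference)]]
  )
}

# Per-replicate delta-Ct values (target - reference, paired by replicate id).
replicate_dct <- function(ct_table, strain, target, reference = "ACT1") {
  ct_table <- tibble::as_tibble(ct_table)
  if (!"melt_ok" %in% names(ct_table)) ct_table$melt_ok <- TRUE
  sub <- dplyr::filter(ct_table, .data$strain == !!strain, .data$melt_ok)
  t_rows <- sub[sub$gene == target, c("replicate", "ct")]
  r_rows <- sub[sub$gene == reference, c("replicate", "ct")]
  paired <- dplyr::inner_join(t_rows, r_rows, by = "replicate",
                              suffix = c("_t", "_r"))
  unpaired <- nrow(t_rows) + nrow(r_rows) - 2 * nrow(paired)
  if (unpaired > 0) {
    warning(unpaired, " unpaired reaction(s) for strain ", strain, " dropped")
  }
  paired$ct_t - paired$ct_r
}

#' Compare relative expression between two strains
#'
#' Two-sided t test on replicate-level log2 fold changes — equivalently on
#' per-replicate delta-Ct values (target minus reference, paired by
#' replicate id), whose difference between strains is the delta-delta-Ct.
#' Statistics are computed on the log scale because fold changes are
#' log-normal under Gaussian Ct noise.
#'
#' @param ct_table a Ct tibble (see [ddct()]).
#' @param strain1,strain2 the two strains to compare.
#' @param target target gene id.
#' @param reference reference gene id.
#' @param var_equal pooled-variance Student's t (default `TRUE`).
#' @return A one-row tibble: `strain1`, `strain2`, `fold_ratio`
#'   (strain1 relative to strain2), `t`, `df`, `p_value`, `n1`, `n2`.
#' @export
compare_expression <- function(ct_table, strain1, strain2, target,
                               reference = "ACT1", var_equal = TRUE) {
  d1 <- replicate_dct(ct_table, strain1, target, reference)
  d2 <- replicate_dct(ct_table, strain2, target, reference)
  if (length(d1) < 2 || length(d2) < 2) {
    abort_locusecho("need >= 2 replicate-level values per strain")
  }
  if (stats::sd(c(d1 - mean(d1), d2 - mean(d2))) == 0 &&
      isTRUE(all.equal(mean(d1), mean(d2)))) {
    return(tibble::tibble(strain1 = strain1, strain2 = strain2,
                          fold_ratio = 1, t = 0,
                          df = length(d1) + length(d2) - 2, p_value = 1,
                          n1 = length(d1), n2 = length(d2)))
  }
  tt <- stats::t.test(d1, d2, var.equal = var_equal, alternative = "two.sided")
  tibble::tibble(strain1 = strain1, strain2 = strain2,
                 fold_ratio = 2^(-(mean(d1) - mean(d2))),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, n1 = length(d1), n2 = length(d2))
}
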