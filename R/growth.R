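#' Growth index of one dilution-series spot row
#'
#' Sums the per-dilution growth scores of one spotting-assay replicate.
#' Scores are bounded in `[0, 1]` (0 = no growth, 1 = confluent), so the
#' index ranges from 0 to the number of dilution steps and is monotone in
#' every score.
#'
#' @param scores numeric vector of per-dilution scores in `[0, 1]`.
#' @return A single numeric index.
#' @export
#' @examples
#' growth_index(c(1, 1, 1, 0.5, 0)) # 3.5
growth_index <- function(scores) {
  if (length(scores) == 0) abort_locusecho("`scores` is empty")
  if (any(is.na(scores)) || any(scores < 0 | scores > 1)) {
    abort_locusecho("scores must lie in [0, 1] with no missing values")
  }
  sum(scores)
}

#' Per-replicate growth indices from a score table
#'
#' @param scores a tibble with columns `strain`, `condition`, `replicate`,
#'   `dilution`, `score` (the [simulate_growth()] schema; an additional
#'   `bio_rep`/`tech_rep` pair may replace `replicate`, in which case
#'   technical replicates are averaged into biological ones).
#' @return A tibble: `strain`, `condition`, `replicate`, `index`.
#' @export
growth_indices <- function(scores) {
  scores <- tibble::as_tibble(scores)
  if (!"replicate" %in% names(scores) &&
      all(c("bio_rep", "tech_rep") %in% names(scores))) {
    scores <- scores |>
      dplyr::group_by(.data$strain, .data$condition, .data$bio_rep,
                      .data$dilution) |>
      dplyr::summarise(score = mean(.data$score), .groups = "drop") |>
      dplyr::rename(replicate = "bio_rep")
  }
  scores |>
    dplyr::group_by(.data$strain, .data$condition, .data$replicate) |>
    dplyr::summarise(index = growth_index(.data$score), .groups = "drop")
}

#' Relative growth under stress versus control
#'
#' For each strain, the mean stress-condition growth index divided by the
#' mean control-condition index (e.g. growth at 40 °C relative to 30 °C).
#' A strain whose control index is zero gets `NA` (undefined, reported via
#' warning — never coerced to 0).
#'
#' @param scores a score tibble (see [growth_indices()]).
#' @param control,stress condition labels.
#' @return A tibble: `strain`, `control_index`, `stress_index`,
#'   `relative_growth`, `n_control`, `n_stress`.
#' @export
relative_growth <- function(scores, control = "30C", stress = "40C") {
  idx <- growth_indices(scores)
  have <- unique(idx$condition)
  if (!all(c(control, stress) %in% have)) {
    abort_locusecho(paste0("conditions not found in scores: ",
                           paste(setdiff(c(control, stress), have), collapse = ", ")))
  }
  wide <- idx |>
    dplyr::filter(.data$condition %in% c(control, stress)) |>
    dplyr::group_by(.data$strain, .data$condition) |>
    dplyr::summarise(mean_index = mean(.data$index), n = dplyr::n(),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("mean_index", "n"))
  out <- tibble::tibble(
    strain = wide$strain,
    control_index = wide[[paste0("mean_index_", control)]],
    stress_index = wide[[paste0("mean_index_", stress)]],
    n_control = wide[[paste0("n_", control)]],
    n_stress = wide[[paste0("n_", stress)]]
  )
  out$relative_growth <- ifelse(out$control_index > 0,
                                out$stress_index / out$control_index,
                                NA_real_)
  if (any(is.na(out$relative_growth))) {
    warning("zero control growth for strain(s): ",
            paste(out$strain[is.na(out$relative_growth)], collapse = ", "),
            "; relative growth undefined")
  }
  out
}

#' Student's t comparison of a mutant against wild type
#'
#' Two-sample, two-sided t test on per-replicate values (growth indices or
#' relative-growth replicates), pooled variance by default to match the
#' classic Student's test; Welch available via `var_equal = FALSE`.
#'
#' @param mutant,wt numeric vectors of replicate values (>= 2 each).
#' @param var_equal pooled-variance Student's t (default `TRUE`).
#' @param alpha significance level (default 0.05).
#' @return A one-row tibble: `mean_mutant`, `mean_wt`, `sem_mutant`,
#'   `sem_wt`, `t`, `df`, `p_value`, `significant`.
#' @export
compare_to_wt <- function(mutant, wt, var_equal = TRUE, alpha = 0.05) {
  if (length(mutant) < 2 || length(wt) < 2) {
    abort_locusecho("need >= 2 replicates per group")
  }
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  if (isTRUE(all.equal(c(mutant - mean(mutant), wt - mean(wt)),
                       rep(0, length(mutant) + length(wt)))) &&
      isTRUE(all.equal(mean(mutant), mean(wt)))) {
    # identical constant groups: t = 0 by convention, nothing to reject
    return(tibble::tibble(mean_mutant = mean(mutant), mean_wt = mean(wt),
                          sem_mutant = sem(mutant), sem_wt = sem(wt),
                          t = 0, df = length(mutant) + length(wt) - 2,
                          p_value = 1, significant = FALSE))
  }
  tt <- stats::t.test(mutant, wt, var.equal = var_equal,
                      alternative = "two.sided")
  tibble::tibble(mean_mutant = mean(mutant), mean_wt = mean(wt),
                 sem_mutant = sem(mutant), sem_wt = sem(wt),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 significant = tt$p.value < alpha)
}

#' Growth statistics for every strain versus wild type
#'
#' Convenience wrapper: per-replicate growth indices for one condition,
#' then [compare_to_wt()] for each non-WT strain. Biological/technical
#' replicate columns are collapsed to biological replicates first (see
#' [growth_indices()]).
#'
#' @param scores a score tibble.
#' @param wt_strain wild-type strain id.
#' @param condition condition to test.
#' @param ... passed to [compare_to_wt()].
#' @return A tibble with one row per mutant strain.
#' @export
growth_vs_wt <- function(scores, wt_strain = "WT", condition = "40C", ...) {
  idx <- dplyr::filter(growth_indices(scores), .data$condition == !!condition)
  if (!wt_strain %in% idx$strain) {
    abort_locusecho(paste0("wild-type strain not in scores: ", wt_strain))
  }
  wt <- idx$index[idx$strain == wt_strain]
  idx |>
    dplyr::filter(.data$strain != wt_strain) |>
    dplyr::group_by(strain = .data$strain) |>
    dplyr::summarise(compare_to_wt(.data$index, wt, ...), .groups = "drop")
}

#' Locus-layout heatmap of relative growth
#'
#' Arranges per-strain relative-growth values into the locus layout: one
#' row per focal locus, columns `-1` (centromere-side neighbor deletion),
#' `FT` (focal freeze–thaw gene deletion), `+1` (telomere-side neighbor
#' deletion). Essential neighbors cannot be deleted; their cells carry
#' `NA` with status `"essential"`, never 0.
#'
#' @param results a tibble with columns `strain`, `relative_growth`
#'   (e.g. from [relative_growth()]).
#' @param layout a tibble with columns `locus`, `position` (one of
#'   `"-1"`, `"FT"`, `"+1"`), `strain`, `essential`; defaults to the
#'   packaged freeze–thaw layout ([freeze_thaw_layout()]).
#' @return An object of class `growth_heatmap`: list with `matrix` (locus x
#'   position), `status` (character matrix: `"ok"`, `"essential"`,
#'   `"missing"`), `layout`.
#' @export
locus_growth_heatmap <- function(results, layout = freeze_thaw_layout()) {
  layout <- tibble::as_tibble(layout)
  joined <- dplyr::left_join(layout, results[, c("strain", "relative_growth")],
                             by = "strain")
  loci <- unique(layout$locus)
  pos <- c("-1", "FT", "+1")
  m <- matrix(NA_real_, nrow = length(loci), ncol = length(pos),
              dimnames = list(loci, pos))
  status <- matrix("missing", nrow = length(loci), ncol = length(pos),
                   dimnames = list(loci, pos))
  for (i in seq_len(nrow(joined))) {
    r <- joined$locus[i]; cc <- joined$position[i]
    if (isTRUE(joined$essential[i])) {
      status[r, cc] <- "essential"
    } else if (!is.na(joined$relative_growth[i])) {
      m[r, cc] <- joined$relative_growth[i]
      status[r, cc] <- "ok"
    }
  }
  structure(list(matrix = m, status = status, layout = layout),
            class = "growth_heatmap")
}

#' @export
print.growth_heatmap <- function(x, ...) {
  cat("<growth_heatmap> relative growth, loci x (-1, FT, +1)\n")
  print(round(x$matrix, 3))
  ess <- which(x$status == "essential", arr.ind = TRUE)
  if (nrow(ess) > 0) {
    cat("essential (not deletable): ",
        paste(sprintf("%s[%s]", rownames(x$matrix)[ess[, 1]],
                      colnames(x$matrix)[ess[, 2]]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot the locus-layout growth heatmap
#'
#' @param object a `growth_heatmap`.
#' @param ... unused.
#' @return A ggplot object; essential cells are hatched with an "E".
#' @method autoplot growth_heatmap
#' @export
autoplot.growth_heatmap <- function(object, ...) {
  df <- tibble::as_tibble(object$matrix, rownames = "locus") |>
    tidyr::pivot_longer(-"locus", names_to = "position",
                        values_to = "relative_growth")
  st <- tibble::as_tibble(object$status, rownames = "locus") |>
    tidyr::pivot_longer(-"locus", names_to = "position", values_to = "status")
  df$status <- st$status
  df$locus <- factor(df$locus, levels = rev(rownames(object$matrix)))
  df$position <- factor(df$position, levels = colnames(object$matrix))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$locus,
                                   fill = .data$relative_growth)) +
    ggplot2::geom_tile(color = "grey40") +
    ggplot2::geom_text(data = df[df$status == "essential", ],
                       ggplot2::aes(x = .data$position, y = .data$locus,
                                    label = "E"), inherit.aes = FALSE) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "position relative to freeze-thaw gene", y = "locus",
                  fill = "rel. growth") +
    ggplot2::theme_minimal()
}

#' Deletion-strain layout of the six freeze–thaw loci
#'
#' One row per deletion strain in the locus screen: the focal freeze–thaw
#' gene and its −1 (centromeric) and +1 (telomeric) neighbors, with the
#' essential flags that make the RRN5 and CCL1 deletions unavailable.
#'
#' @return A tibble: `locus`, `position`, `strain`, `essential`.
#' @export
freeze_thaw_layout <- function() {
  ann <- scer_gene_order()
  purrr::map_dfr(freeze_thaw_genes(), function(g) {
    nb <- neighborhood(ann, g, k = 1)
    cen <- nb[nb$direction == "centromeric", ]
    tel <- nb[nb$direction == "telomeric", ]
    tibble::tibble(
      locus = g,
      position = c("-1", "FT", "+1"),
      strain = c(cen$neighbor, g, tel$neighbor),
      essential = c(cen$is_essential, FALSE, tel$is_essential)
    )
  })
}
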