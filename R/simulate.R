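#' Simulation configuration for synthetic locus data
#'
#' Bundles every knob of the synthetic-data generator: the genome geometry,
#' the correlation-decay kernel that couples neighboring genes, the
#' condition-block layout of the expression samples, and the RNG seed.
#'
#' The co-expression kernel is \eqn{\rho(d) = c_0 + a_0 \exp(-d/\lambda_0)}
#' on midpoint-to-midpoint genomic distance \eqn{d} (bp): `decay_amplitude`
#' (\eqn{a_0}) is the correlation between immediately adjacent genes in
#' excess of the genome-wide baseline `baseline_corr` (\eqn{c_0}), and
#' `decay_length` (\eqn{\lambda_0}, bp) is the distance over which that
#' excess falls by a factor of \eqn{e}.
#'
#' @param n_chromosomes number of chromosomes to simulate.
#' @param genes_per_chromosome genes per chromosome.
#' @param mean_gene_length mean gene length in bp.
#' @param mean_intergenic_gap mean gap between consecutive genes in bp.
#' @param decay_amplitude kernel amplitude \eqn{a_0} in `[0, 1]`.
#' @param decay_length kernel decay length \eqn{\lambda_0} in bp (> 0).
#' @param baseline_corr distance-independent baseline correlation \eqn{c_0};
#'   `decay_amplitude + baseline_corr` must not exceed 1.
#' @param n_blocks number of condition blocks (e.g. distinct stressors).
#' @param samples_per_block expression samples per block.
#' @param noise_sd marginal standard deviation of expression values
#'   (log-ratio units).
#' @param block_shift_sd standard deviation of the per-block, per-gene mean
#'   shifts that emulate condition-specific regulation.
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 7, seed = 42)
#' ann <- simulate_genome(cfg)
sim_config <- function(n_chromosomes = 2,
                       genes_per_chromosome = 25,
                       mean_gene_length = 1500,
                       mean_intergenic_gap = 500,
                       decay_amplitude = 0.6,
                       decay_length = 5000,
                       baseline_corr = 0.1,
                       n_blocks = 5,
                       samples_per_block = 8,
                       noise_sd = 1,
                       block_shift_sd = 0.25,
                       seed = 1L) {
  counts <- c(n_chromosomes = n_chromosomes,
              genes_per_chromosome = genes_per_chromosome,
              n_blocks = n_blocks, samples_per_block = samples_per_block)
  if (any(counts < 1) || any(counts != round(counts))) {
    abort_locusecho("all counts (chromosomes, genes, blocks, samples) must be integers >= 1")
  }
  if (decay_amplitude < 0 || decay_amplitude > 1) {
    abort_locusecho("`decay_amplitude` must lie in [0, 1]")
  }
  if (decay_amplitude + baseline_corr > 1 + 1e-12) {
    abort_locusecho("`decay_amplitude` + `baseline_corr` must not exceed 1 (correlations are bounded by 1)")
  }
  if (decay_length <= 0) abort_locusecho("`decay_length` must be > 0")
  if (mean_gene_length <= 0 || mean_intergenic_gap < 0) {
    abort_locusecho("gene lengths must be positive and gaps non-negative")
  }
  if (noise_sd <= 0) abort_locusecho("`noise_sd` must be > 0")
  structure(
    list(n_chromosomes = as.integer(n_chromosomes),
         genes_per_chromosome = as.integer(genes_per_chromosome),
         mean_gene_length = mean_gene_length,
         mean_intergenic_gap = mean_intergenic_gap,
         decay_amplitude = decay_amplitude,
         decay_length = decay_length,
         baseline_corr = baseline_corr,
         n_blocks = as.integer(n_blocks),
         samples_per_block = as.integer(samples_per_block),
         noise_sd = noise_sd,
         block_shift_sd = block_shift_sd,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate an ordered gene annotation
#'
#' Draws non-overlapping genes chromosome by chromosome, with exponential
#' gene lengths and intergenic gaps, random strands, and one centromere per
#' chromosome placed in a gap near the middle of the gene array.
#'
#' @param config a [sim_config()].
#' @return An annotation tibble (see [annotation_table()]): columns
#'   `feature`, `gene_id`, `chromosome`, `start`, `end` (1-based inclusive),
#'   `strand`, `is_essential`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    chroms <- purrr::map(seq_len(config$n_chromosomes), function(ci) {
      n <- config$genes_per_chromosome
      lens <- pmax(150, round(stats::rexp(n, 1 / config$mean_gene_length)))
      gaps <- pmax(50, round(stats::rexp(n, 1 / max(config$mean_intergenic_gap, 1))))
      starts <- cumsum(gaps) + cumsum(dplyr::lag(lens, default = 0))
      genes <- tibble::tibble(
        feature = "gene",
        gene_id = sprintf("g%d_%03d", ci, seq_len(n)),
        chromosome = sprintf("chr%d", ci),
        start = starts,
        end = starts + lens - 1,
        strand = sample(c("+", "-"), n, replace = TRUE),
        is_essential = FALSE
      )
      # centromere sits in the intergenic gap following the middle gene
      mid <- max(1, floor(n / 2))
      cen_start <- genes$end[mid] + 10
      cen <- tibble::tibble(
        feature = "centromere",
        gene_id = sprintf("CEN%d", ci),
        chromosome = sprintf("chr%d", ci),
        start = cen_start,
        end = cen_start + 117,
        strand = "+",
        is_essential = FALSE
      )
      dplyr::bind_rows(genes, cen)
    })
    annotation_table(dplyr::bind_rows(chroms))
  })
}

# Kernel correlation matrix for one chromosome's gene midpoints.
decay_kernel_matrix <- function(midpoints, amplitude, decay_length, baseline) {
  d <- abs(outer(midpoints, midpoints, "-"))
  k <- baseline + amplitude * exp(-d / decay_length)
  diag(k) <- 1
  k
}

#' Simulate a block-structured expression matrix over an annotation
#'
#' For each chromosome, samples are drawn from a multivariate normal whose
#' gene-pair correlation follows the configured decay kernel
#' \eqn{c_0 + a_0 \exp(-d/\lambda_0)} on midpoint distance; genes on
#' different chromosomes are uncorrelated. Each condition block adds its own
#' per-gene mean shift, so within-block correlations follow the kernel while
#' blocks differ in level, as stress time-courses do.
#'
#' If the assembled correlation matrix is not positive semi-definite for an
#' unusual gene spacing it is repaired by nearest-PSD projection
#' ([Matrix::nearPD()]) and a message is emitted.
#'
#' @param annotation annotation tibble from [simulate_genome()] /
#'   [load_annotation()].
#' @param config a [sim_config()].
#' @return An [expression_matrix()] object.
#' @export
simulate_expression <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- dplyr::filter(annotation, .data$feature == "gene")
  if (nrow(genes) == 0) abort_locusecho("annotation contains no genes")
  blocks <- sprintf("block_%02d", seq_len(config$n_blocks))
  manifest <- tibble::tibble(
    sample_id = sprintf("%s_s%02d",
                        rep(blocks, each = config$samples_per_block),
                        rep(seq_len(config$samples_per_block), config$n_blocks)),
    block_name = rep(blocks, each = config$samples_per_block)
  )
  n_samples <- nrow(manifest)

  values <- with_seed(config$seed + 1L, {
    per_chrom <- lapply(split(genes, genes$chromosome), function(g) {
      g <- dplyr::arrange(g, .data$start)
      mids <- (g$start + g$end) / 2
      k <- decay_kernel_matrix(mids, config$decay_amplitude,
                               config$decay_length, config$baseline_corr)
      ev <- eigen(k, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8) {
        k <- as.matrix(Matrix::nearPD(k, corr = TRUE)$mat)
        message("correlation kernel repaired by nearest-PSD projection on ",
                g$chromosome[1])
      }
      sigma <- config$noise_sd^2 * k
      shifts <- matrix(stats::rnorm(config$n_blocks * nrow(g),
                                    sd = config$block_shift_sd),
                       nrow = config$n_blocks)
      vals <- matrix(NA_real_, nrow = nrow(g), ncol = n_samples,
                     dimnames = list(g$gene_id, manifest$sample_id))
      for (b in seq_len(config$n_blocks)) {
        idx <- which(manifest$block_name == blocks[b])
        draw <- MASS::mvrnorm(length(idx), mu = shifts[b, ], Sigma = sigma)
        vals[, idx] <- t(matrix(draw, nrow = length(idx)))
      }
      vals
    })
    do.call(rbind, per_chrom)[genes$gene_id, , drop = FALSE]
  })
  expression_matrix(values, manifest)
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Generates cycle-threshold values for one target gene and one reference
#' gene across strains such that the expected 2^-ddCt estimate for each
#' strain (relative to the calibrator, normalized to the reference) equals
#' the requested fold change. Reference-gene Ct is constant in expectation
#' across strains; Gaussian cycle noise is added to every reaction.
#'
#' @param true_fold_changes named numeric vector, strain -> fold change
#'   relative to the calibrator strain (all > 0).
#' @param n_replicates replicates per strain and gene (>= 2).
#' @param seed RNG seed.
#' @param target,reference gene labels used in the table.
#' @param calibrator calibrator strain; defaults to the first name of
#'   `true_fold_changes`. Its fold is renormalized to 1.
#' @param ct_sd Gaussian Ct noise, in cycles.
#' @param base_ct expected target Ct in the calibrator strain.
#' @param reference_ct expected reference-gene Ct in every strain.
#' @param melt_fail_rate probability that a reaction fails the melt-curve
#'   check (`melt_ok = FALSE`).
#' @return A Ct tibble: `strain`, `gene`, `replicate`, `ct`, `melt_ok`.
#' @export
simulate_qpcr <- function(true_fold_changes, n_replicates = 4, seed = 1L,
                          target = "YCP4", reference = "ACT1",
                          calibrator = names(true_fold_changes)[1],
                          ct_sd = 0.1, base_ct = 24, reference_ct = 17,
                          melt_fail_rate = 0) {
  if (is.null(names(true_fold_changes)) || any(!nzchar(names(true_fold_changes)))) {
    abort_locusecho("`true_fold_changes` must be a named numeric vector (strain -> fold)")
  }
  if (any(true_fold_changes <= 0)) abort_locusecho("fold changes must be > 0")
  if (n_replicates < 2) abort_locusecho("`n_replicates` must be >= 2")
  if (!calibrator %in% names(true_fold_changes)) {
    abort_locusecho("`calibrator` must be one of the strains in `true_fold_changes`")
  }
  folds <- true_fold_changes / true_fold_changes[[calibrator]]
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      strain = names(folds),
      gene = c(target, reference),
      replicate = seq_len(n_replicates)
    )
    mu <- ifelse(grid$gene == reference, reference_ct,
                 base_ct - log2(folds[grid$strain]))
    dplyr::mutate(
      grid,
      ct = mu + stats::rnorm(nrow(grid), sd = ct_sd),
      melt_ok = stats::runif(nrow(grid)) >= melt_fail_rate
    )
  })
}

#' Simulate spotting-assay dilution grids with known relative fitness
#'
#' Emulates 5-fold serial-dilution spotting assays: each strain gets a
#' control grid and a stressed grid of per-dilution growth scores in
#' `[0, 1]`. The baseline control profile declines with dilution step; the
#' stressed profile is the control profile scaled by the strain's relative
#' fitness, so the expected stressed growth index equals
#' `relative_fitness * control index` (exactly 0 when fitness is 0).
#'
#' @param relative_fitness named numeric vector, strain -> stressed/control
#'   fitness ratio (>= 0).
#' @param n_dilutions dilution steps per spot row (>= 3).
#' @param n_replicates replicates per strain and condition.
#' @param seed RNG seed.
#' @param noise_sd Gaussian score noise before clamping to `[0, 1]`.
#' @param control_label,stress_label condition labels in the output.
#' @return A tibble: `strain`, `condition`, `replicate`, `dilution`, `score`.
#' @export
simulate_growth <- function(relative_fitness, n_dilutions = 5,
                            n_replicates = 3, seed = 1L, noise_sd = 0.05,
                            control_label = "30C", stress_label = "40C") {
  if (is.null(names(relative_fitness))) {
    abort_locusecho("`relative_fitness` must be a named numeric vector (strain -> ratio)")
  }
  if (any(relative_fitness < 0)) abort_locusecho("fitness ratios must be >= 0")
  if (n_dilutions < 3) abort_locusecho("`n_dilutions` must be >= 3")
  base <- 0.9 * (1 - (seq_len(n_dilutions) - 1) / n_dilutions)
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      strain = names(relative_fitness),
      condition = c(control_label, stress_label),
      replicate = seq_len(n_replicates),
      dilution = seq_len(n_dilutions)
    )
    ratio <- relative_fitness[grid$strain]
    mu <- ifelse(grid$condition == control_label, base[grid$dilution],
                 ratio * base[grid$dilution])
    score <- clamp01(mu + stats::rnorm(nrow(grid), sd = noise_sd))
    score[grid$condition == stress_label & ratio == 0] <- 0
    dplyr::mutate(grid, score = score)
  })
}
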