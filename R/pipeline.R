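#' Assemble a pipeline run configuration
#'
#' Either a simulation config (everything is generated with known ground
#' truth) or paths to real inputs (annotation, expression matrix +
#' manifest, and optionally growth scores, Ct tables and synteny orders).
#'
#' @param simulation a [sim_config()], or `NULL` when real inputs are given.
#' @param annotation_path,expression_path,manifest_path input files (used
#'   when `simulation` is `NULL`).
#' @param growth_path,qpcr_path,synteny_path optional extra inputs (CSV /
#'   TSV in the module schemas); the corresponding stages run only when
#'   supplied (or when simulating).
#' @param focal_genes focal gene ids; defaults to the six freeze–thaw genes
#'   when running on a real annotation, or to mid-chromosome genes when
#'   simulating.
#' @param k neighbors per side (default 3).
#' @param decay_model passed to [fit_decay()].
#' @param out_dir output directory for the report bundle.
#' @param seed seed recorded in the manifest and used for any simulation.
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulation = NULL, annotation_path = NULL,
                       expression_path = NULL, manifest_path = NULL,
                       growth_path = NULL, qpcr_path = NULL,
                       synteny_path = NULL, focal_genes = NULL, k = 3,
                       decay_model = "exponential", out_dir = "locusecho_out",
                       seed = 1L) {
  if (is.null(simulation) &&
      (is.null(annotation_path) || is.null(expression_path) ||
       is.null(manifest_path))) {
    abort_locusecho("supply either `simulation` or annotation/expression/manifest paths")
  }
  structure(list(simulation = simulation, annotation_path = annotation_path,
                 expression_path = expression_path,
                 manifest_path = manifest_path, growth_path = growth_path,
                 qpcr_path = qpcr_path, synteny_path = synteny_path,
                 focal_genes = focal_genes, k = k, decay_model = decay_model,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

stage_msg <- function(stage, ...) message("[", stage, "] ", ...)

#' Run the full neighborhood-analysis pipeline
#'
#' Orchestrates simulate-or-load, mapping, per-block correlation, decay
#' fitting, and — when the inputs exist — growth quantification, 2^-ddCt
#' qPCR and synteny alignment. All stage outputs are flat TSVs under
#' `config$out_dir`, plus a JSON manifest recording the seed, package and R
#' versions, and input hashes; reruns with the same seed and inputs are
#' byte-identical.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory stage results
#'   (`annotation`, `expression`, `neighborhoods`, `profiles`, `fits`, and
#'   optionally `growth`, `qpcr`, `synteny`), plus `out_dir`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hashes <- list()

  if (!is.null(config$simulation)) {
    sim <- config$simulation
    stage_msg("simulate", "genome + expression under seed ", sim$seed)
    annotation <- simulate_genome(sim)
    expr <- simulate_expression(annotation, sim)
    write_annotation_gff3(annotation, file.path(config$out_dir, "annotation.gff3"))
    write_expression(expr, file.path(config$out_dir, "expression.tsv"),
                     file.path(config$out_dir, "manifest.tsv"))
  } else {
    stage_msg("load", "annotation and expression from disk")
    annotation <- load_annotation(config$annotation_path)
    expr <- load_expression(config$expression_path, config$manifest_path)
    for (p in c(config$annotation_path, config$expression_path,
                config$manifest_path)) {
      hashes[[basename(p)]] <- unname(tools::md5sum(p))
    }
  }

  genes <- dplyr::filter(annotation, .data$feature == "gene")
  focal <- config$focal_genes
  if (is.null(focal)) {
    focal <- if (all(freeze_thaw_genes() %in% genes$gene_id)) {
      freeze_thaw_genes()
    } else {
      # mid-chromosome genes have full neighborhoods on both sides
      genes |>
        dplyr::group_by(.data$chromosome) |>
        dplyr::slice(ceiling(dplyr::n() / 2)) |>
        dplyr::pull(.data$gene_id)
    }
  }
  stage_msg("map", length(focal), " focal gene(s), k = ", config$k)
  nbhds <- purrr::map(focal, ~neighborhood(annotation, .x, k = config$k))
  names(nbhds) <- focal
  nb_all <- dplyr::bind_rows(nbhds)
  readr::write_tsv(nb_all, file.path(config$out_dir, "neighborhoods.tsv"))

  blocks <- unique(expr$manifest$block_name)
  stage_msg("correlate", length(blocks), " block(s) x ", length(focal),
            " locus/loci")
  profiles <- purrr::map(nbhds, function(nb) {
    fg <- unique(nb$focal)
    if (!fg %in% rownames(expr$values)) {
      stage_msg("correlate", "focal ", fg, " absent from matrix; skipped")
      return(NULL)
    }
    purrr::map_dfr(blocks, function(b) {
      suppressMessages(locus_profile(expr, nb, block = b))
    })
  })
  profiles <- purrr::compact(profiles)
  prof_all <- dplyr::bind_rows(profiles)
  readr::write_tsv(prof_all, file.path(config$out_dir, "profiles.tsv"))

  heatmaps <- purrr::map(profiles, function(p) {
    tryCatch(condition_heatmap(p), error = function(e) NULL)
  })
  hm_tsv <- purrr::imap_dfr(purrr::compact(heatmaps), function(h, fg) {
    tibble::as_tibble(h$matrix, rownames = "gene") |>
      dplyr::mutate(focal = fg, .before = 1)
  })
  readr::write_tsv(hm_tsv, file.path(config$out_dir, "heatmaps.tsv"))

  stage_msg("fit", "decay curves per locus")
  fits <- purrr::map(profiles, function(p) {
    pooled <- dplyr::select(p, distance = "signed_distance", "pcc")
    tryCatch(fit_decay(pooled, model = config$decay_model),
             error = function(e) {
               stage_msg("fit", "skipped: ", conditionMessage(e))
               NULL
             })
  })
  fits_tbl <- purrr::imap_dfr(purrr::compact(fits), function(f, fg) {
    dplyr::mutate(glance(f), locus = fg, .before = 1)
  })
  readr::write_tsv(fits_tbl, file.path(config$out_dir, "decay_fits.tsv"))
  n_conv <- sum(!fits_tbl$flat_flag)
  stage_msg("fit", nrow(fits_tbl), " fit(s), ", n_conv, " non-flat")

  out <- list(annotation = annotation, expression = expr,
              neighborhoods = nb_all, profiles = prof_all, fits = fits,
              out_dir = config$out_dir)

  if (!is.null(config$growth_path) || !is.null(config$simulation)) {
    stage_msg("growth", "quantifying spotting grids")
    growth_scores <- if (!is.null(config$growth_path)) {
      hashes[[basename(config$growth_path)]] <-
        unname(tools::md5sum(config$growth_path))
      readr::read_csv(config$growth_path, show_col_types = FALSE)
    } else {
      simulate_growth(stats::setNames(c(1, 0.5, 1.4),
                                      c("WT", "sensitive", "resistant")),
                      n_replicates = 6, seed = config$seed + 10L)
    }
    growth <- relative_growth(growth_scores)
    stats_tbl <- growth_vs_wt(growth_scores, wt_strain = growth$strain[1])
    readr::write_tsv(dplyr::left_join(growth, stats_tbl, by = "strain"),
                     file.path(config$out_dir, "growth_results.tsv"))
    out$growth <- growth
  }

  if (!is.null(config$qpcr_path) || !is.null(config$simulation)) {
    stage_msg("qpcr", "2^-ddCt quantification")
    ct <- if (!is.null(config$qpcr_path)) {
      hashes[[basename(config$qpcr_path)]] <-
        unname(tools::md5sum(config$qpcr_path))
      readr::read_csv(config$qpcr_path, show_col_types = FALSE)
    } else {
      simulate_qpcr(c(WT = 1, mrpl32_del = 2, cit2_del = 2),
                    n_replicates = 4, seed = config$seed + 20L,
                    target = "KANr")
    }
    target <- setdiff(unique(ct$gene), "ACT1")[1]
    qp <- ddct(ct, target = target, calibrator = unique(ct$strain)[1])
    readr::write_tsv(qp, file.path(config$out_dir, "qpcr_results.tsv"))
    out$qpcr <- qp
  }

  if (!is.null(config$synteny_path) || !is.null(config$simulation)) {
    stage_msg("synteny", "anchored gene-order alignment")
    orders <- if (!is.null(config$synteny_path)) {
      hashes[[basename(config$synteny_path)]] <-
        unname(tools::md5sum(config$synteny_path))
      readr::read_tsv(config$synteny_path, show_col_types = FALSE)
    } else {
      ycp4_synteny_panel()
    }
    anchor <- if ("YCP4" %in% orders$family) "YCP4" else orders$family[1]
    st <- align_orders(orders, anchor = anchor)
    readr::write_tsv(conservation_summary(st),
                     file.path(config$out_dir, "synteny_summary.tsv"))
    out$synteny <- st
  }

  manifest <- list(
    seed = config$seed,
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("locusecho")),
    k = config$k, decay_model = config$decay_model,
    focal_genes = focal, input_hashes = hashes,
    simulated = !is.null(config$simulation)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  stage_msg("done", "bundle written to ", config$out_dir)
  invisible(out)
}
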