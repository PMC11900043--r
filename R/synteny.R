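# Longest monotone subsequence indices (O(n^2), lists here are tiny).
lis_keep <- function(pos) {
  n <- length(pos)
  if (n == 0) return(integer(0))
  len <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      if (pos[j] < pos[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L; prev[i] <- j
      }
    }
  }
  i <- which.max(len)
  keep <- integer(0)
  while (i > 0) { keep <- c(i, keep); i <- prev[i] }
  keep
}

#' Align per-species gene orders on an anchor gene
#'
#' Builds a synteny table in the gene-order-browser "pillar" style: the
#' columns are the reference species' genes around the anchor, and every
#' other species is scanned for order-consistent homologs. A column is
#' called `present` in a species when a gene of the same homology family
#' occurs in that species' list and its placement is consistent with the
#' column order (longest order-consistent chain, orientation-agnostic, so
#' a reversed gene list gives identical calls); otherwise `lost`. Genes of
#' the species that fall between two adjacent present columns and belong to
#' no column family are recorded as insertions.
#'
#' @param orders a tibble with columns `species`, `position` (integer rank
#'   along the chromosome/scaffold), `gene_id`, `family` (homology family
#'   label shared across species). A reconstructed ancestor is treated as
#'   just another species (conventionally labelled `"ancestor"`).
#' @param anchor homology family of the anchor gene; must be present in
#'   the reference species.
#' @param reference reference species; defaults to the first species in
#'   `orders`.
#' @param window optional number of reference genes kept on each side of
#'   the anchor (default: all provided rows).
#' @return An object of class `synteny_table`: list with `columns`
#'   (tibble: `column`, `family`, `ref_gene`), `cells` (tibble: `species`,
#'   `column`, `family`, `status`, `gene_id`, `position`), `insertions`
#'   (tibble: `species`, `after_column`, `after_family`, `n_inserted`),
#'   `anchor`, `reference`.
#' @export
align_orders <- function(orders, anchor, reference = NULL, window = NULL) {
  orders <- tibble::as_tibble(orders)
  req <- c("species", "position", "gene_id", "family")
  if (!all(req %in% names(orders))) {
    abort_locusecho(paste0("`orders` needs columns: ", paste(req, collapse = ", ")))
  }
  species <- unique(orders$species)
  reference <- reference %||% species[1]
  ref <- dplyr::arrange(dplyr::filter(orders, .data$species == reference),
                        .data$position)
  a_idx <- which(ref$family == anchor)
  if (length(a_idx) == 0) {
    abort_locusecho(paste0("anchor family absent from reference species: ", anchor))
  }
  a_idx <- a_idx[1]
  if (!is.null(window)) {
    keep <- seq(max(1, a_idx - window), min(nrow(ref), a_idx + window))
    ref <- ref[keep, ]
  }
  columns <- tibble::tibble(column = seq_len(nrow(ref)),
                            family = ref$family, ref_gene = ref$gene_id)

  cells <- list(); insertions <- list()
  for (sp in species) {
    tab <- dplyr::arrange(dplyr::filter(orders, .data$species == sp),
                          .data$position)
    hit <- match(columns$family, tab$family)  # first occurrence per family
    found <- which(!is.na(hit))
    pos <- hit[found]
    # orientation-agnostic order consistency: best monotone chain
    fwd <- lis_keep(pos)
    rev_ <- lis_keep(-pos)
    keep_local <- if (length(fwd) >= length(rev_)) fwd else rev_
    present_cols <- found[keep_local]
    status <- rep("lost", nrow(columns))
    status[present_cols] <- "present"
    cells[[sp]] <- tibble::tibble(
      species = sp, column = columns$column, family = columns$family,
      status = status,
      gene_id = ifelse(status == "present", tab$gene_id[hit], NA_character_),
      position = ifelse(status == "present", tab$position[hit], NA_integer_)
    )
    # insertions between adjacent present columns
    pp <- hit[present_cols]
    if (length(pp) >= 2) {
      for (i in seq_len(length(pp) - 1)) {
        lo <- min(pp[i], pp[i + 1]); hi <- max(pp[i], pp[i + 1])
        if (hi - lo > 1) {
          between <- tab[(lo + 1):(hi - 1), ]
          extra <- sum(!between$family %in% columns$family)
          if (extra > 0) {
            insertions[[length(insertions) + 1]] <- tibble::tibble(
              species = sp,
              after_column = columns$column[present_cols[i]],
              after_family = columns$family[present_cols[i]],
              n_inserted = extra
            )
          }
        }
      }
    }
  }
  structure(list(columns = columns,
                 cells = dplyr::bind_rows(cells),
                 insertions = if (length(insertions) > 0) {
                   dplyr::bind_rows(insertions)
                 } else {
                   tibble::tibble(species = character(), after_column = integer(),
                                  after_family = character(), n_inserted = integer())
                 },
                 anchor = anchor, reference = reference,
                 species = species),
            class = "synteny_table")
}

#' @export
print.synteny_table <- function(x, ...) {
  cat("<synteny_table> anchor ", x$anchor, ", reference ", x$reference, ": ",
      nrow(x$columns), " columns x ", length(x$species), " species, ",
      nrow(x$insertions), " insertion event(s)\n", sep = "")
  wide <- tidyr::pivot_wider(x$cells[, c("species", "family", "status")],
                             names_from = "family", values_from = "status")
  print(wide)
  invisible(x)
}

#' Per-column conservation counts of a synteny table
#'
#' @param table a [align_orders()] result.
#' @return A tibble per column: `column`, `family`, `n_present`, `n_lost`,
#'   `n_inserted_adjacent` (species with >= 1 insertion in a gap flanking
#'   the column). `n_present + n_lost` equals the number of species.
#' @export
conservation_summary <- function(table) {
  stopifnot(inherits(table, "synteny_table"))
  counts <- table$cells |>
    dplyr::group_by(column = .data$column, family = .data$family) |>
    dplyr::summarise(n_present = sum(.data$status == "present"),
                     n_lost = sum(.data$status == "lost"), .groups = "drop")
  ins <- table$insertions
  adj <- vapply(counts$column, function(cl) {
    flanking <- ins$after_column %in% c(cl, cl - 1L)
    length(unique(ins$species[flanking]))
  }, integer(1))
  dplyr::mutate(counts, n_inserted_adjacent = adj)
}

#' Cross-species neighborhood correlation profiles
#'
#' Applies [locus_profile()] to one expression matrix per species, mapping
#' the reference neighborhood through an ortholog table first. Neighbors
#' with no ortholog (or absent from a species' matrix) appear with
#' `pcc = NA` so the cross-species heatmap keeps one row per gene, order
#' maintained.
#'
#' @param expr_list named list of [expression_matrix()] objects, one per
#'   species.
#' @param nbhd a [neighborhood()] tibble from the reference species.
#' @param ortholog_map optional tibble `species`, `gene_id` (reference id),
#'   `ortholog` (id in that species' matrix); identity mapping by default.
#' @param block block name passed to [locus_profile()] (default all
#'   samples).
#' @return A tibble of profiles with a `species` column.
#' @export
cross_species_profiles <- function(expr_list, nbhd, ortholog_map = NULL,
                                   block = NULL) {
  stopifnot(is.list(expr_list), !is.null(names(expr_list)))
  focal <- unique(nbhd$focal)
  purrr::imap_dfr(expr_list, function(expr, sp) {
    nb <- nbhd
    if (!is.null(ortholog_map)) {
      om <- dplyr::filter(ortholog_map, .data$species == sp)
      trans <- function(ids) {
        out <- om$ortholog[match(ids, om$gene_id)]
        ifelse(is.na(out), ids, out)
      }
      nb$neighbor <- trans(nb$neighbor)
      nb$focal <- trans(nb$focal)
    }
    present <- nb$neighbor %in% rownames(expr$values)
    prof <- suppressMessages(
      locus_profile(expr, nb[present, , drop = FALSE], block = block)
    )
    missing_rows <- nb[!present, , drop = FALSE]
    if (nrow(missing_rows) > 0) {
      prof <- dplyr::bind_rows(prof, tibble::tibble(
        focal = unique(nb$focal), block = prof$block[1] %||% "all",
        neighbor = missing_rows$neighbor, offset = missing_rows$offset,
        signed_distance = missing_rows$signed_distance,
        pcc = NA_real_, n_pairs = 0L
      ))
    }
    dplyr::mutate(dplyr::arrange(prof, .data$offset), species = sp,
                  .before = 1)
  })
}

#' Synthetic toy synteny panel around YCP4
#'
#' A small hand-constructed cross-species gene-order panel (a synthetic
#' stand-in for a gene-order-browser export) encoding the published
#' conservation pattern at the YCP4 locus: YCP4 is retained in all
#' lineages and the reconstructed ancestor except *T. blattae* and
#' *E. gossypii*; its telomeric neighbor CIT2 — like the more distal RER1,
#' PGS1 and LBD16 — is retained everywhere; the centromeric MRPL32
#' arrangement is interrupted by insertions in the distant lineages.
#'
#' @return A tibble in the [align_orders()] input schema.
#' @export
ycp4_synteny_panel <- function() {
  ref_families <- c("LBD16", "PGS1", "RER1", "CDC10", "MRPL32", "YCP4",
                    "CIT2", "YCR006C", "YCR007C")
  make_species <- function(sp, families, inserted_after = character(),
                           n_inserted = integer()) {
    genes <- character(0); fams <- character(0)
    for (f in families) {
      genes <- c(genes, paste0(sp, "_", f)); fams <- c(fams, f)
      hit <- which(inserted_after == f)
      if (length(hit) == 1) {
        k <- n_inserted[hit]
        genes <- c(genes, sprintf("%s_novel%02d_%s", sp, seq_len(k), f))
        fams <- c(fams, sprintf("%s_private_%s_%d", sp, f, seq_len(k)))
      }
    }
    tibble::tibble(species = sp, position = seq_along(genes),
                   gene_id = genes, family = fams)
  }
  dplyr::bind_rows(
    make_species("S_cerevisiae", ref_families),
    make_species("S_paradoxus", ref_families),
    make_species("S_mikatae", ref_families),
    make_species("S_kudriavzevii", ref_families),
    make_species("N_castellii",
                 c("LBD16", "PGS1", "RER1", "MRPL32", "YCP4", "CIT2",
                   "YCR007C"),
                 inserted_after = "MRPL32", n_inserted = 1L),
    make_species("T_blattae",
                 c("LBD16", "PGS1", "RER1", "MRPL32", "CIT2", "YCR007C"),
                 inserted_after = "MRPL32", n_inserted = 2L),
    make_species("E_gossypii",
                 c("LBD16", "PGS1", "RER1", "CIT2"),
                 inserted_after = "RER1", n_inserted = 1L),
    make_species("ancestor", ref_families)
  )
}

#' Plot a synteny alignment
#'
#' Pillar-style alignment: one row per species, one column per reference
#' gene; present cells are filled arrows-as-tiles, lost cells are gaps, and
#' insertion counts are printed between columns.
#'
#' @param object a `synteny_table`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot synteny_table
#' @export
autoplot.synteny_table <- function(object, ...) {
  cells <- object$cells
  cells$species <- factor(cells$species, levels = rev(object$species))
  cells$family <- factor(cells$family, levels = object$columns$family)
  anchor_fam <- object$anchor
  cells$role <- ifelse(cells$family == anchor_fam, "anchor", "neighbor")
  ins <- object$insertions
  p <- ggplot2::ggplot(cells[cells$status == "present", ],
                       ggplot2::aes(x = .data$family, y = .data$species,
                                    fill = .data$role)) +
    ggplot2::geom_tile(color = "white", linewidth = 1) +
    ggplot2::scale_fill_manual(values = c(anchor = "#08306B",
                                          neighbor = "#6BAED6")) +
    ggplot2::labs(x = "reference gene order", y = NULL, fill = NULL,
                  title = paste0("synteny around ", anchor_fam)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (nrow(ins) > 0) {
    ins$species <- factor(ins$species, levels = levels(cells$species))
    ins$x <- ins$after_column + 0.5
    p <- p + ggplot2::geom_text(
      data = ins,
      ggplot2::aes(x = .data$x, y = .data$species,
                   label = paste0("+", .data$n_inserted)),
      inherit.aes = FALSE, size = 3)
  }
  p
}
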