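#' Build a validated, ordered annotation table
#'
#' The annotation table is the package's ordered gene map: one row per gene
#' or non-ORF feature (centromeres, telomeric repeats), sorted by chromosome
#' and start coordinate. Coordinates are 1-based inclusive, the convention
#' of GFF3; all distance arithmetic uses gene midpoints, which is invariant
#' to the coordinate convention.
#'
#' @param df a data frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, and optionally `strand`, `feature` (defaults `"gene"`),
#'   `is_essential` (defaults `FALSE`).
#' @return A tibble sorted by (chromosome, start) with the full column set.
#' @export
annotation_table <- function(df) {
  req <- c("gene_id", "chromosome", "start", "end")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort_locusecho(paste0("annotation is missing column(s): ",
                           paste(missing_cols, collapse = ", ")))
  }
  df <- tibble::as_tibble(df)
  if (!"feature" %in% names(df)) df$feature <- "gene"
  if (!"strand" %in% names(df)) df$strand <- "+"
  if (!"is_essential" %in% names(df)) df$is_essential <- FALSE
  bad <- which(df$end < df$start)
  if (length(bad) > 0) {
    abort_locusecho(paste0("end < start for record(s): ",
                           paste(df$gene_id[bad], collapse = ", ")))
  }
  genes <- df[df$feature == "gene", ]
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    abort_locusecho(paste0("duplicate gene_id(s): ", paste(unique(dup), collapse = ", ")))
  }
  cen_counts <- table(df$chromosome[df$feature == "centromere"])
  if (any(cen_counts > 1)) {
    abort_locusecho(paste0("more than one centromere on: ",
                           paste(names(cen_counts)[cen_counts > 1], collapse = ", ")))
  }
  out <- dplyr::arrange(df, .data$chromosome, .data$start)
  dplyr::select(out, "feature", "gene_id", "chromosome", "start", "end",
                "strand", "is_essential", dplyr::everything())
}

gff3_feature_types <- c(gene = "gene", centromere = "centromere",
                        telomeric_repeat = "telomeric_repeat")

#' Read an annotation from GFF3 or a plain gene table
#'
#' Accepts either a GFF3 file (tab-delimited, `##gff-version` header,
#' attributes carrying `ID`/`Name` and optionally `essential=true`) or a
#' headered TSV gene table with the [annotation_table()] columns. Feature
#' types other than gene / centromere / telomeric_repeat are ignored with a
#' message stating how many were dropped. Records with `end < start` raise
#' an error naming the offending line numbers.
#'
#' @param path file path.
#' @return An [annotation_table()] tibble.
#' @export
load_annotation <- function(path) {
  if (!file.exists(path)) abort_locusecho(paste0("no such file: ", path))
  lines <- readr::read_lines(path)
  is_gff <- any(grepl("^##gff-version", lines)) || grepl("\\.gff3?$", path)
  if (!is_gff) {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    return(annotation_table(df))
  }
  body_idx <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(body_idx) == 0) abort_locusecho("GFF3 file has no feature rows")
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  n_col <- vapply(fields, length, integer(1))
  if (any(n_col != 9)) {
    abort_locusecho(paste0("malformed GFF3 row(s) at line(s): ",
                           paste(body_idx[n_col != 9], collapse = ", ")))
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.numeric(m[, 4]))
  end <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | end < start)
  if (length(bad) > 0) {
    abort_locusecho(paste0("malformed coordinates (end < start or non-numeric) at line(s): ",
                           paste(body_idx[bad], collapse = ", ")))
  }
  type <- m[, 3]
  keep <- type %in% gff3_feature_types
  if (any(!keep)) {
    message(sum(!keep), " record(s) with unhandled feature types ignored (",
            paste(unique(type[!keep]), collapse = ", "), ")")
  }
  attr_field <- m[, 9]
  get_attr <- function(attrs, key) {
    vapply(attrs, function(a) {
      mm <- regmatches(a, regexpr(paste0("(?:^|;)", key, "=([^;]*)"), a, perl = TRUE))
      if (length(mm) == 0) return(NA_character_)
      sub(paste0("^;?", key, "="), "", mm)
    }, character(1), USE.NAMES = FALSE)
  }
  ids <- get_attr(attr_field, "Name")
  ids2 <- get_attr(attr_field, "ID")
  ids[is.na(ids)] <- ids2[is.na(ids)]
  ess <- tolower(get_attr(attr_field, "essential")) %in% "true"
  df <- tibble::tibble(
    feature = type, gene_id = ids, chromosome = m[, 1],
    start = start, end = end,
    strand = ifelse(m[, 7] %in% c("+", "-"), m[, 7], "+"),
    is_essential = ess
  )[keep, ]
  annotation_table(df)
}

#' Write an annotation table as GFF3
#'
#' @param annotation an [annotation_table()] tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  annotation <- annotation_table(annotation)
  attrs <- sprintf("ID=%s;Name=%s%s", annotation$gene_id, annotation$gene_id,
                   ifelse(annotation$is_essential, ";essential=true", ""))
  rows <- sprintf("%s\tlocusecho\t%s\t%d\t%d\t.\t%s\t.\t%s",
                  annotation$chromosome, annotation$feature,
                  as.integer(annotation$start), as.integer(annotation$end),
                  annotation$strand, attrs)
  readr::write_lines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Extract the ±k gene neighborhood around a focal gene
#'
#' Neighbors are taken in gene-rank order along the chromosome (strand is
#' ignored), up to `k` on each side; fewer are returned without error at
#' chromosome ends. Signed distance is neighbor midpoint minus focal
#' midpoint in bp. When the chromosome carries a centromere feature each
#' neighbor is labelled `"centromeric"` or `"telomeric"` according to
#' whether it lies closer to or farther from the centromere than the focal
#' gene; without a centromere the labels fall back to `"left"`/`"right"` in
#' coordinate order.
#'
#' @param annotation an [annotation_table()] tibble.
#' @param focal focal gene id (must be present).
#' @param k maximum neighbors per side (default 3).
#' @return A tibble: `focal`, `neighbor`, `offset` (signed gene rank),
#'   `signed_distance` (bp), `direction`, `is_essential`.
#' @export
#' @examples
#' ann <- scer_gene_order()
#' neighborhood(ann, "YCP4", k = 1)
neighborhood <- function(annotation, focal, k = 3) {
  annotation <- annotation_table(annotation)
  genes <- dplyr::filter(annotation, .data$feature == "gene")
  hit <- which(genes$gene_id == focal)
  if (length(hit) == 0) {
    abort_locusecho(paste0("focal gene not found in annotation: ", focal))
  }
  chrom <- genes$chromosome[hit]
  g <- dplyr::arrange(dplyr::filter(genes, .data$chromosome == chrom), .data$start)
  i <- which(g$gene_id == focal)
  idx <- seq(max(1, i - k), min(nrow(g), i + k))
  idx <- idx[idx != i]
  mid <- (g$start + g$end) / 2
  cen <- dplyr::filter(annotation, .data$feature == "centromere",
                       .data$chromosome == chrom)
  if (nrow(cen) == 1) {
    cen_mid <- (cen$start + cen$end) / 2
    direction <- ifelse(abs(mid[idx] - cen_mid) < abs(mid[i] - cen_mid),
                        "centromeric", "telomeric")
  } else {
    direction <- ifelse(idx < i, "left", "right")
  }
  tibble::tibble(
    focal = focal,
    neighbor = g$gene_id[idx],
    offset = as.integer(idx - i),
    signed_distance = mid[idx] - mid[i],
    direction = direction,
    is_essential = g$is_essential[idx]
  )
}

#' Packaged S. cerevisiae gene-order fixture around the freeze–thaw loci
#'
#' Returns the ordered gene map for the six freeze–thaw loci (AQY1, ATH1,
#' CAR1, POG1, PUT1, YCP4) with their flanking genes, centromeres and the
#' relevant telomeric repeats, as shipped in `inst/extdata`. Gene
#' identities, rank order along each chromosome arm, strands and essential
#' flags (RRN5, CCL1) follow the S. cerevisiae genome annotation; base-pair
#' coordinates are approximate, order-preserving stand-ins adequate for
#' rank-order neighborhood analysis.
#'
#' @return An [annotation_table()] tibble.
#' @export
scer_gene_order <- function() {
  path <- system.file("extdata", "scer_gene_order.tsv", package = "locusecho",
                      mustWork = TRUE)
  load_annotation(path)
}

#' The six freeze–thaw genes
#'
#' Deletion of each of these genes increases S. cerevisiae viability after
#' a freeze–thaw cycle; they are the default focal set of the pipeline.
#'
#' @return A character vector of six gene names.
#' @export
freeze_thaw_genes <- function() {
  c("AQY1", "ATH1", "CAR1", "POG1", "PUT1", "YCP4")
}
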