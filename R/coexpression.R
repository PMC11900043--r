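#' Construct an expression matrix with a condition-block manifest
#'
#' The container for gene-by-sample expression values (log-ratio units)
#' together with a manifest mapping every sample to a named condition block
#' (one stressor time series, or the cell-cycle course). Missing values are
#' permitted and handled downstream by pairwise complete-case deletion.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param manifest data frame with columns `sample_id`, `block_name`
#'   covering every column of `values`.
#' @return An object of class `expr_matrix`: a list with `values` and
#'   `manifest`.
#' @export
expression_matrix <- function(values, manifest) {
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values))) {
    abort_locusecho("`values` must be a matrix with gene rownames and sample colnames")
  }
  manifest <- tibble::as_tibble(manifest)
  if (!all(c("sample_id", "block_name") %in% names(manifest))) {
    abort_locusecho("manifest needs columns `sample_id` and `block_name`")
  }
  uncovered <- setdiff(colnames(values), manifest$sample_id)
  if (length(uncovered) > 0) {
    abort_locusecho(paste0("sample(s) absent from manifest: ",
                           paste(uncovered, collapse = ", ")))
  }
  if (anyDuplicated(rownames(values))) abort_locusecho("duplicate gene ids")
  manifest <- manifest[match(colnames(values), manifest$sample_id), ]
  structure(list(values = values, manifest = manifest), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples in ", length(unique(x$manifest$block_name)), " block(s)\n",
      sep = "")
  invisible(x)
}

#' Tidy an expression matrix into long format
#'
#' @param x an [expression_matrix()].
#' @param ... unused.
#' @return A tibble: `gene_id`, `sample_id`, `block_name`, `value`.
#' @method tidy expr_matrix
#' @export
tidy.expr_matrix <- function(x, ...) {
  long <- tibble::as_tibble(x$values, rownames = "gene_id")
  long <- tidyr::pivot_longer(long, -"gene_id", names_to = "sample_id",
                              values_to = "value")
  dplyr::left_join(long, x$manifest, by = "sample_id")
}

#' Read an expression matrix and its block manifest from TSV
#'
#' The matrix file is tab-delimited with gene ids in the first column and
#' one column per sample; the manifest file has columns `sample_id` and
#' `block_name`. Per-block sample counts are reported via `message()`;
#' empty blocks (named in the manifest but without samples) trigger a
#' warning and are dropped.
#'
#' @param matrix_path,manifest_path file paths.
#' @return An [expression_matrix()].
#' @export
load_expression <- function(matrix_path, manifest_path) {
  mat_df <- readr::read_tsv(matrix_path, show_col_types = FALSE)
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE)
  genes <- mat_df[[1]]
  if (anyDuplicated(genes)) abort_locusecho("duplicate gene ids in matrix file")
  values <- as.matrix(mat_df[, -1, drop = FALSE])
  rownames(values) <- genes
  em <- expression_matrix(values, manifest)
  counts <- dplyr::count(em$manifest, .data$block_name)
  message("loaded ", nrow(values), " genes x ", ncol(values), " samples; ",
          "blocks: ", paste(sprintf("%s=%d", counts$block_name, counts$n),
                            collapse = ", "))
  n_missing <- sum(is.na(values))
  if (n_missing > 0) message(n_missing, " missing value(s) flagged")
  em
}

#' Write an expression matrix and manifest to TSV
#'
#' @param expr an [expression_matrix()].
#' @param matrix_path,manifest_path output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(expr, matrix_path, manifest_path) {
  df <- tibble::as_tibble(expr$values, rownames = "gene_id")
  readr::write_tsv(df, matrix_path)
  readr::write_tsv(expr$manifest, manifest_path)
  invisible(matrix_path)
}

#' Pearson correlation with pairwise complete-case handling
#'
#' Product-moment correlation on the complete observation pairs of two
#' series. Returns `NA` (an undefined-correlation signal, never 0) when
#' fewer than `min_pairs` complete pairs remain or either series has zero
#' variance on them.
#'
#' @param x,y numeric vectors of equal length.
#' @param min_pairs minimum complete pairs for a defined value (default 3).
#' @return A single numeric PCC in `[-1, 1]`, or `NA_real_`.
#' @export
#' @examples
#' pcc(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
pcc <- function(x, y, min_pairs = 3) {
  if (length(x) != length(y)) abort_locusecho("`x` and `y` must have equal length")
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < min_pairs) return(NA_real_)
  xs <- x[ok]; ys <- y[ok]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
  if (all(xs == ys)) return(1)  # self-comparison is exactly 1
  stats::cor(xs, ys)
}

#' Focal-vs-neighbor correlation profile within one condition block
#'
#' Computes the Pearson correlation between the focal gene's expression and
#' each neighbor's expression across the samples of one block. Neighbors
#' absent from the matrix are skipped with a message; the focal gene must
#' be present.
#'
#' @param expr an [expression_matrix()].
#' @param nbhd a [neighborhood()] tibble.
#' @param block block name present in the manifest, or `NULL` to use all
#'   samples.
#' @param min_pairs passed to [pcc()].
#' @return A tibble: `focal`, `block`, `neighbor`, `offset`,
#'   `signed_distance`, `pcc`, `n_pairs`.
#' @export
locus_profile <- function(expr, nbhd, block = NULL, min_pairs = 3) {
  stopifnot(inherits(expr, "expr_matrix"))
  focal <- unique(nbhd$focal)
  stopifnot(length(focal) == 1)
  if (!focal %in% rownames(expr$values)) {
    abort_locusecho(paste0("focal gene absent from expression matrix: ", focal))
  }
  if (is.null(block)) {
    cols <- seq_len(ncol(expr$values))
    block <- "all"
  } else {
    cols <- which(expr$manifest$block_name == block)
    if (length(cols) == 0) abort_locusecho(paste0("no samples in block: ", block))
  }
  absent <- setdiff(nbhd$neighbor, rownames(expr$values))
  if (length(absent) > 0) {
    message("neighbor(s) absent from matrix, skipped: ",
            paste(absent, collapse = ", "))
  }
  present <- dplyr::filter(nbhd, !.data$neighbor %in% absent)
  fx <- expr$values[focal, cols]
  purrr::pmap_dfr(
    list(present$neighbor, present$offset, present$signed_distance),
    function(nb, off, dist) {
      ny <- expr$values[nb, cols]
      ok <- stats::complete.cases(fx, ny)
      tibble::tibble(focal = focal, block = block, neighbor = nb,
                     offset = off, signed_distance = dist,
                     pcc = pcc(fx, ny, min_pairs = min_pairs),
                     n_pairs = sum(ok))
    }
  )
}

#' Locus-average correlation over a profile
#'
#' Averages the focal-vs-neighbor PCCs of one correlation profile (e.g.
#' over the cell-cycle time course), excluding undefined entries. With
#' `method = "fisher_z"` the mean is taken on the Fisher z scale and
#' transformed back.
#'
#' @param profile a [locus_profile()] tibble (column `pcc`).
#' @param method `"mean"` (unweighted arithmetic mean, the default) or
#'   `"fisher_z"`.
#' @return A single numeric, or `NA_real_` (with a warning) when no entry
#'   is defined.
#' @export
locus_average_pcc <- function(profile, method = c("mean", "fisher_z")) {
  method <- match.arg(method)
  r <- profile$pcc[!is.na(profile$pcc)]
  if (length(r) == 0) {
    warning("no defined neighbor correlations; locus average is undefined")
    return(NA_real_)
  }
  switch(method,
         mean = mean(r),
         fisher_z = tanh(mean(atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)))))
}

#' Condition-clustered correlation heatmap matrix
#'
#' Assembles per-block correlation profiles for one locus into the heatmap
#' layout: rows are the focal gene and its neighbors in genomic order
#' (the focal row is the self-comparison, PCC = 1), columns are condition
#' blocks reordered by average-linkage hierarchical clustering on the
#' Euclidean distance between block PCC vectors. Row order is never
#' clustered. Cells with |PCC| > `strong_threshold` are flagged as strong.
#'
#' @param profiles a tibble of [locus_profile()] rows over >= 2 blocks for
#'   one focal gene.
#' @param strong_threshold |PCC| above which a cell is marked strong
#'   (default 0.5).
#' @return An object of class `correlation_heatmap`: list with `matrix`
#'   (genes x blocks, genomic row order, clustered column order), `strong`
#'   (logical matrix), `hclust`, `focal`.
#' @export
condition_heatmap <- function(profiles, strong_threshold = 0.5) {
  focal <- unique(profiles$focal)
  stopifnot(length(focal) == 1)
  blocks <- unique(profiles$block)
  if (length(blocks) < 2) abort_locusecho("need profiles for >= 2 blocks")
  rows <- dplyr::distinct(profiles, .data$neighbor, .data$signed_distance)
  rows <- dplyr::bind_rows(rows,
                           tibble::tibble(neighbor = focal, signed_distance = 0))
  rows <- dplyr::arrange(rows, .data$signed_distance)
  m <- matrix(NA_real_, nrow = nrow(rows), ncol = length(blocks),
              dimnames = list(rows$neighbor, blocks))
  for (i in seq_len(nrow(profiles))) {
    m[profiles$neighbor[i], profiles$block[i]] <- profiles$pcc[i]
  }
  m[focal, ] <- 1
  all_missing <- colSums(!is.na(m)) == 0
  if (any(all_missing)) {
    warning("dropping all-missing block(s): ",
            paste(colnames(m)[all_missing], collapse = ", "))
    m <- m[, !all_missing, drop = FALSE]
  }
  if (ncol(m) < 2) abort_locusecho("fewer than 2 usable blocks after dropping")
  cols_for_dist <- m
  cols_for_dist[is.na(cols_for_dist)] <- 0  # distance on observed pattern
  hc <- stats::hclust(stats::dist(t(cols_for_dist)), method = "average")
  m <- m[, hc$order, drop = FALSE]
  structure(list(matrix = m,
                 strong = !is.na(m) & abs(m) > strong_threshold,
                 hclust = hc, focal = focal),
            class = "correlation_heatmap")
}

#' @export
print.correlation_heatmap <- function(x, ...) {
  cat("<correlation_heatmap> focal ", x$focal, ": ", nrow(x$matrix),
      " genes (genomic order) x ", ncol(x$matrix),
      " blocks (clustered order)\n", sep = "")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Plot a condition-clustered correlation heatmap
#'
#' Rows keep genomic order (focal gene marked), columns keep the clustered
#' block order; strong cells (|PCC| above the threshold used at build time)
#' get a dot.
#'
#' @param object a [condition_heatmap()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot correlation_heatmap
#' @export
autoplot.correlation_heatmap <- function(object, ...) {
  df <- tibble::as_tibble(object$matrix, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "block", values_to = "pcc")
  strong <- tibble::as_tibble(object$strong, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "block", values_to = "strong")
  df$strong <- strong$strong
  df$gene <- factor(df$gene, levels = rev(rownames(object$matrix)))
  df$block <- factor(df$block, levels = colnames(object$matrix))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$block, y = .data$gene,
                                   fill = .data$pcc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[df$strong & !is.na(df$strong), ],
                        size = 1) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1),
                                  na.value = "grey85") +
    ggplot2::labs(x = "condition block (clustered)",
                  y = "gene (genomic order)", fill = "PCC",
                  title = paste0(object$focal, " neighborhood")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
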