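#' Build the N x M conservation matrix
#'
#' For every query protein and every genome, the genome's stop-to-stop
#' ORFs are searched with affine-gap local alignment and the best raw
#' score is normalized by the query's self-score. The result is the
#' phyletic profile underlying the conservation heatmaps.
#'
#' @param queries list of protein records (each with `id`, `residues`), or
#'   a named character vector of peptides.
#' @param genomes list of DNA records (each with `id`, `residues`), or a
#'   named character vector of genome sequences.
#' @param scheme a [scoring_scheme()].
#' @param min_score minimum raw alignment score (see [best_hit()]).
#' @param min_aa minimum ORF peptide length (see [extract_orfs()]).
#' @return An object of class `conservation_matrix`: `values` (N x M
#'   numeric matrix, rows = proteins, columns = genomes, all in \[0, 1\]),
#'   `entries` (list of per-cell `conservation_entry`), `provenance`.
#' @export
build_matrix <- function(queries, genomes, scheme = scoring_scheme(),
                         min_score = 40L, min_aa = 30L) {
  queries <- .as_records(queries)
  genomes <- .as_records(genomes)
  qids <- vapply(queries, `[[`, character(1), "id")
  gids <- vapply(genomes, `[[`, character(1), "id")
  if (anyDuplicated(qids)) stop("duplicate query ids")
  if (anyDuplicated(gids)) stop("duplicate genome ids")
  qids <- unname(qids)
  gids <- unname(gids)
  values <- matrix(0, nrow = length(qids), ncol = length(gids),
                   dimnames = list(qids, gids))
  entries <- list()
  for (j in seq_along(genomes)) {
    orfs <- extract_orfs(genomes[[j]], min_aa = min_aa)
    if (nrow(orfs) == 0) {
      warning("genome '", gids[j], "' has no ORFs >= ", min_aa,
              " aa: column of zeros")
    }
    for (i in seq_along(queries)) {
      e <- if (nrow(orfs) == 0) {
        suppressWarnings(best_hit(queries[[i]], orfs, scheme, min_score))
      } else {
        best_hit(queries[[i]], orfs, scheme, min_score)
      }
      values[i, j] <- e$conservation
      entries[[paste(qids[i], gids[j], sep = "\r")]] <- e
    }
  }
  structure(list(values = values, entries = entries,
                 provenance = list(scheme = scheme$name,
                                   gap_open = scheme$gap_open,
                                   gap_extend = scheme$gap_extend,
                                   min_score = min_score, min_aa = min_aa,
                                   timestamp = format(Sys.time()))),
            class = "conservation_matrix")
}

#' @keywords internal
.as_records <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    return(Map(function(id, s) list(id = id, residues = s), names(x),
               unname(x)))
  }
  x
}

#' @export
print.conservation_matrix <- function(x, ...) {
  cat(sprintf("conservation_matrix: %d proteins x %d genomes (%s, min_score %d)\n",
              nrow(x$values), ncol(x$values), x$provenance$scheme,
              x$provenance$min_score))
  invisible(x)
}

#' Export a conservation matrix as TSV (4 decimals)
#'
#' Header row holds the genome ids, first column the protein ids; values
#' are serialized with exactly 4 decimals so export/import round-trips at
#' that precision.
#'
#' @param matrix a `conservation_matrix` or a plain numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_matrix <- function(matrix, path) {
  v <- if (inherits(matrix, "conservation_matrix")) matrix$values else matrix
  fmt <- matrix(sprintf("%.4f", v), nrow = nrow(v), dimnames = dimnames(v))
  tab <- cbind(protein_id = rownames(v), as.data.frame(fmt,
                                                       check.names = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a conservation matrix written by [export_matrix()]
#'
#' @param path TSV path.
#' @return A `conservation_matrix` (provenance marked as imported).
#' @export
import_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (length(unique(ncols)) != 1) {
    stop("ragged rows in matrix file: ", path)
  }
  header <- parts[[1]][-1]
  ids <- vapply(parts[-1], `[`, character(1), 1)
  vals <- t(vapply(parts[-1], function(p) as.numeric(p[-1]),
                   numeric(length(header))))
  if (anyNA(vals)) stop("non-numeric cell in matrix file: ", path)
  if (any(vals < 0 | vals > 1)) stop("values outside [0, 1] in: ", path)
  dimnames(vals) <- list(ids, header)
  structure(list(values = vals, entries = NULL,
                 provenance = list(scheme = "imported", min_score = NA,
                                   min_aa = NA,
                                   timestamp = format(Sys.time()))),
            class = "conservation_matrix")
}

#' Render the conservation heatmap
#'
#' Blue-white-red ramp mapped linearly on \[0, 1\]. With clustering
#' enabled, rows/columns are reordered by hierarchical clustering
#' (Euclidean distance, complete linkage) with dendrograms; otherwise the
#' input order is preserved, which lets pathway-grouped gene orders from
#' curated figures be reproduced. A sidecar TSV of the final row and
#' column order is always written next to the image so ordering is
#' testable without parsing the image.
#'
#' @param matrix a `conservation_matrix` or numeric matrix.
#' @param out image path (`.png` or `.pdf`).
#' @param cluster_rows,cluster_cols enable hierarchical clustering
#'   (default off).
#' @param ... passed on to [pheatmap::pheatmap()].
#' @return Invisibly, a list with `row_order` and `col_order` (ids in
#'   display order) and `order_file`.
#' @export
render_heatmap <- function(matrix, out, cluster_rows = FALSE,
                           cluster_cols = FALSE, ...) {
  v <- if (inherits(matrix, "conservation_matrix")) matrix$values else matrix
  if (!dir.exists(dirname(out))) stop("unwritable path: ", out)
  ramp <- grDevices::colorRampPalette(c("blue", "white", "red"))(100)
  ph <- pheatmap::pheatmap(v, color = ramp,
                           breaks = seq(0, 1, length.out = 101),
                           cluster_rows = cluster_rows,
                           cluster_cols = cluster_cols,
                           clustering_distance_rows = "euclidean",
                           clustering_distance_cols = "euclidean",
                           clustering_method = "complete",
                           filename = out, silent = TRUE, ...)
  row_order <- if (cluster_rows) rownames(v)[ph$tree_row$order] else rownames(v)
  col_order <- if (cluster_cols) colnames(v)[ph$tree_col$order] else colnames(v)
  order_file <- paste0(out, ".order.tsv")
  n <- max(length(row_order), length(col_order))
  pad <- function(x) c(x, rep("", n - length(x)))
  write.table(data.frame(row_order = pad(row_order),
                         col_order = pad(col_order)),
              order_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(row_order = row_order, col_order = col_order,
                 order_file = order_file))
}
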