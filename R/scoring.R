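#' Construct a protein scoring scheme
#'
#' Bundles a symmetric substitution matrix with affine gap penalties: a gap
#' of length k costs `gap_open + k * gap_extend`. The default is BLOSUM62
#' with gap open 11 and gap extend 1 (classic tblastn defaults). The scheme
#' records whether the matrix is diagonal-dominant (every diagonal entry is
#' the maximum of its row), which guarantees that conservation scores never
#' exceed 1.
#'
#' @param matrix integer substitution matrix with identical row/column
#'   names; `NULL` selects BLOSUM62.
#' @param gap_open,gap_extend non-negative integers, `gap_extend <= gap_open`.
#' @param name scheme label.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11L, gap_extend = 1L,
                           name = NULL) {
  if (is.null(matrix)) {
    matrix <- .blosum62()
    name <- name %||% "BLOSUM62"
  }
  name <- name %||% "custom"
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (!identical(rownames(matrix), colnames(matrix))) {
    stop("substitution matrix must have identical row and column names")
  }
  if (!isTRUE(all(matrix == t(matrix)))) {
    stop("substitution matrix must be symmetric")
  }
  gap_open <- as.integer(gap_open)
  gap_extend <- as.integer(gap_extend)
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  if (gap_extend > gap_open) stop("gap_extend must be <= gap_open")
  mode(matrix) <- "integer"
  dd <- all(vapply(seq_len(nrow(matrix)),
                   function(i) matrix[i, i] == max(matrix[i, ]),
                   logical(1)))
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, name = name,
                 diagonal_dominant = dd),
            class = "scoring_scheme")
}

#' @keywords internal
.blosum62_cache <- new.env(parent = emptyenv())

#' @keywords internal
.blosum62 <- function() {
  if (is.null(.blosum62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum62_cache$m <- e$BLOSUM62
  }
  .blosum62_cache$m
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("scoring_scheme:", x$name,
      sprintf("(%d residues; gap open %d, extend %d%s)\n",
              nrow(x$matrix), x$gap_open, x$gap_extend,
              if (x$diagonal_dominant) "; diagonal-dominant" else ""))
  invisible(x)
}

#' Read an NCBI-format substitution matrix file
#'
#' Parses the plain-text matrix format used by NCBI BLAST (`#` comments,
#' a header row of residue labels, one labelled row per residue).
#'
#' @param path path to the matrix file.
#' @return An integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) stop("not a substitution matrix file: ", path)
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  lab <- vapply(rows, `[`, character(1), 1)
  vals <- t(vapply(rows, function(r) as.integer(r[-1]),
                   integer(length(cols))))
  dimnames(vals) <- list(lab, cols)
  if (!identical(rownames(vals), colnames(vals))) {
    stop("matrix row labels do not match column labels")
  }
  vals
}

#' Self-alignment score of a query (the conservation-score denominator)
#'
#' The ungapped sum of diagonal matrix entries over all residues of the
#' query; under a diagonal-dominant matrix this equals the gapped local
#' self-alignment score.
#'
#' @param query protein string.
#' @param scheme a [scoring_scheme()].
#' @return Integer score.
#' @export
self_score <- function(query, scheme = scoring_scheme()) {
  stopifnot(nzchar(query))
  chars <- strsplit(query, "")[[1]]
  miss <- setdiff(unique(chars), rownames(scheme$matrix))
  if (length(miss) > 0) {
    stop("residue(s) absent from matrix: ", paste(miss, collapse = ", "))
  }
  sum(scheme$matrix[cbind(chars, chars)])
}

# map residues to 0-based matrix indices for the C++ kernels
#' @keywords internal
.residue_idx <- function(s, scheme) {
  chars <- strsplit(s, "")[[1]]
  i <- match(chars, rownames(scheme$matrix))
  if (anyNA(i)) {
    stop("residue(s) absent from matrix: ",
         paste(unique(chars[is.na(i)]), collapse = ", "))
  }
  i - 1L
}
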