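#' Affine-gap Smith-Waterman local alignment of two protein strings
#'
#' Exact optimal local alignment under affine gap costs (a gap of length k
#' costs `gap_open + k * gap_extend`), the deterministic surrogate for the
#' local alignments a translated BLAST search reports. One optimal traceback
#' is returned with fixed tie-breaking (diagonal, then up, then left).
#'
#' @param query,target non-empty protein strings.
#' @param scheme a [scoring_scheme()].
#' @return An object of class `local_alignment`: `score` (>= 0),
#'   `query_span`/`target_span` (0-based half-open), `aligned_pairs`
#'   (two-column matrix of 1-based positions, NA at gaps),
#'   `percent_identity` (identical pairs / aligned columns, gap columns in
#'   the denominator, 2 decimals) and `query_coverage` (span length /
#'   query length, whole percent).
#' @export
sw_align <- function(query, target, scheme = scoring_scheme()) {
  if (!nzchar(query) || !nzchar(target)) {
    stop("query and target must be non-empty")
  }
  res <- sw_align_cpp(.residue_idx(query, scheme),
                      .residue_idx(target, scheme),
                      scheme$matrix, scheme$gap_open, scheme$gap_extend)
  qp <- res$query_pos
  tp <- res$target_pos
  ncol_aln <- length(qp)
  if (res$score <= 0 || ncol_aln == 0) {
    aln <- structure(list(query_id = NA_character_, target_id = NA_character_,
                          score = 0L,
                          query_span = c(0L, 0L), target_span = c(0L, 0L),
                          aligned_pairs = cbind(query = integer(),
                                                target = integer()),
                          percent_identity = NA_real_, query_coverage = 0,
                          n_columns = 0L),
                     class = "local_alignment")
    return(aln)
  }
  qc <- strsplit(query, "")[[1]]
  tc <- strsplit(target, "")[[1]]
  both <- !is.na(qp) & !is.na(tp)
  ident <- sum(qc[qp[both]] == tc[tp[both]])
  qspan <- range(qp, na.rm = TRUE)
  tspan <- range(tp, na.rm = TRUE)
  structure(list(
    query_id = NA_character_, target_id = NA_character_,
    score = res$score,
    query_span = c(qspan[1] - 1L, qspan[2]),
    target_span = c(tspan[1] - 1L, tspan[2]),
    aligned_pairs = cbind(query = qp, target = tp),
    percent_identity = round(100 * ident / ncol_aln, 2),
    query_coverage = round(100 * (qspan[2] - qspan[1] + 1L) / nchar(query)),
    n_columns = ncol_aln), class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf(
    "local_alignment: score %d, %s%% id over %d columns, coverage %s%%\n",
    x$score, format(x$percent_identity, nsmall = 2), x$n_columns,
    x$query_coverage))
  invisible(x)
}

#' @keywords internal
.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

#' Identity and coverage statistics of the optimal local alignment
#'
#' The two statistics reported alongside ortholog assignments: percent
#' identity over aligned columns (gap columns included in the denominator)
#' and percent of the query covered by the aligned span.
#'
#' @param query,target protein strings or records with `residues`.
#' @param scheme a [scoring_scheme()].
#' @return Named numeric vector `c(percent_identity, query_coverage)`.
#' @export
pairwise_stats <- function(query, target, scheme = scoring_scheme()) {
  if (is.list(query)) query <- query$residues
  if (is.list(target)) target <- target$residues
  aln <- sw_align(query, target, scheme)
  c(percent_identity = aln$percent_identity,
    query_coverage = aln$query_coverage)
}

#' Best translated-search hit of a protein query in one genome's ORFs
#'
#' Aligns the query against every ORF peptide and keeps the maximum score
#' at or above `min_score`; ties are broken by smaller forward-strand
#' start, then forward strand over reverse. The best score divided by the
#' query's self-score is the conservation score in \[0, 1\]; with no
#' qualifying hit both are 0.
#'
#' @param query protein string, or a record with `id` and `residues`.
#' @param orfs ORF data.frame from [extract_orfs()] (one genome).
#' @param scheme a [scoring_scheme()].
#' @param min_score minimum raw alignment score to accept (default 40,
#'   which suppresses spurious short-ORF matches in AT-rich genomes).
#' @param prefilter when TRUE, only ORFs sharing at least two length-4
#'   k-mers with the query are aligned (a seed-and-extend shortcut for
#'   very large genomes); exact search over all ORFs is the default.
#' @return A list of class `conservation_entry`: `protein_id`, `genome_id`,
#'   `best_score`, `self_score`, `conservation`, `best_orf` (one-row
#'   data.frame or NULL).
#' @export
best_hit <- function(query, orfs, scheme = scoring_scheme(),
                     min_score = 40L, prefilter = FALSE) {
  qid <- if (is.list(query)) query$id %||% "query" else "query"
  qseq <- if (is.list(query)) query$residues else query
  ss <- self_score(qseq, scheme)
  gid <- if (nrow(orfs) > 0) unique(orfs$genome_id) else NA_character_
  if (length(gid) > 1) stop("orfs must all share one genome_id")
  entry <- function(score, orf) {
    cons <- score / ss
    if (cons > 1) {
      if (scheme$diagonal_dominant) {
        stop("conservation > 1 under a diagonal-dominant scheme")
      }
      warning("conservation clamped to 1")
      cons <- 1
    }
    structure(list(protein_id = qid, genome_id = gid, best_score = score,
                   self_score = ss, conservation = cons, best_orf = orf),
              class = "conservation_entry")
  }
  if (nrow(orfs) == 0) {
    warning("empty ORF list for query '", qid, "'")
    return(entry(0L, NULL))
  }
  if (prefilter) {
    qk <- unique(.kmers(qseq, 4L))
    shared <- vapply(orfs$peptide, function(p) {
      sum(unique(.kmers(p, 4L)) %in% qk)
    }, integer(1))
    orfs <- orfs[shared >= 2L, , drop = FALSE]
    if (nrow(orfs) == 0) return(entry(0L, NULL))
  }
  qidx <- .residue_idx(qseq, scheme)
  tidx <- lapply(orfs$peptide, .residue_idx, scheme = scheme)
  scores <- sw_score_many_cpp(qidx, tidx, scheme$matrix,
                              scheme$gap_open, scheme$gap_extend)
  ok <- scores >= min_score
  if (!any(ok)) return(entry(0L, NULL))
  best <- max(scores[ok])
  cand <- which(scores == best & ok)
  if (length(cand) > 1) {
    ord <- order(orfs$start[cand], orfs$strand[cand] != "+")
    cand <- cand[ord]
  }
  entry(best, orfs[cand[1], , drop = FALSE])
}
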