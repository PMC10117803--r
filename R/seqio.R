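#' @keywords internal
DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' @keywords internal
AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                   "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# codon -> amino acid, standard genetic code (translation table 1)
.codon_table <- local({
  tab <- Biostrings::GENETIC_CODE
  setNames(as.character(tab), names(tab))
})

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Read a FASTA file of DNA or protein sequences
#'
#' Sequences are uppercased on ingestion. For DNA, IUPAC ambiguity codes
#' other than N are mapped to N with a warning; any other character is a
#' parse error reported with its line number. For protein, the 20 standard
#' residues plus X are accepted; the stop symbol `*` is rejected.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return A list of records, each a list with `id` (header token up to the
#'   first whitespace), `description` (remainder of the header) and
#'   `residues` (uppercase string). An empty file yields an empty list.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) return(list())
  hdr <- grepl("^>", lines)
  first_content <- which(nzchar(trimws(lines)))[1]
  if (!hdr[first_content]) {
    stop("malformed FASTA: sequence data before first header at line ",
         first_content)
  }
  idx <- cumsum(hdr)
  recs <- vector("list", sum(hdr))
  hdr_lines <- which(hdr)
  for (k in seq_along(hdr_lines)) {
    h <- sub("^>", "", lines[hdr_lines[k]])
    if (!nzchar(trimws(h))) {
      stop("malformed FASTA header at line ", hdr_lines[k])
    }
    id <- strsplit(trimws(h), "\\s+")[[1]][1]
    desc <- trimws(sub("^\\S+\\s*", "", trimws(h)))
    body_lines <- which(idx == k & !hdr)
    residues <- toupper(gsub("\\s", "", paste(lines[body_lines], collapse = "")))
    if (!nzchar(residues)) {
      stop("record '", id, "' (line ", hdr_lines[k], ") has no residues")
    }
    residues <- .validate_residues(residues, alphabet, id,
                                   lines, body_lines)
    recs[[k]] <- list(id = id, description = desc, residues = residues)
  }
  recs
}

#' @keywords internal
.validate_residues <- function(residues, alphabet, id, lines, body_lines) {
  chars <- strsplit(residues, "")[[1]]
  if (alphabet == "dna") {
    ambi <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
    bad <- !(chars %in% c(DNA_ALPHABET, ambi))
    if (any(bad)) {
      ln <- .offending_line(lines, body_lines, chars, bad)
      stop("illegal DNA character '", chars[which(bad)[1]], "' in record '",
           id, "' at line ", ln)
    }
    if (any(chars %in% ambi)) {
      warning("record '", id, "': ", sum(chars %in% ambi),
              " IUPAC ambiguity code(s) mapped to N")
      chars[chars %in% ambi] <- "N"
      residues <- paste(chars, collapse = "")
    }
  } else {
    bad <- !(chars %in% c(AA_ALPHABET20, "X"))
    if (any(bad)) {
      ln <- .offending_line(lines, body_lines, chars, bad)
      stop("illegal protein character '", chars[which(bad)[1]],
           "' in record '", id, "' at line ", ln)
    }
  }
  residues
}

# locate the file line containing the first offending character
#' @keywords internal
.offending_line <- function(lines, body_lines, chars, bad) {
  pos <- which(bad)[1]
  lens <- nchar(gsub("\\s", "", lines[body_lines]))
  cum <- cumsum(lens)
  body_lines[which(cum >= pos)[1]]
}

#' Write sequence records to FASTA (60-column wrapping)
#'
#' @param records list of records as returned by [read_fasta()], or a named
#'   character vector of residue strings.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- Map(function(id, s) list(id = id, description = "",
                                        residues = s),
                   names(records), unname(records))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    hdr <- if (nzchar(r$description %||% "")) {
      paste0(">", r$id, " ", r$description)
    } else paste0(">", r$id)
    writeLines(hdr, con)
    s <- r$residues
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  invisible(path)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a DNA string
#'
#' @param seq DNA string over A, C, G, T, N.
#' @return The reverse complement; N maps to N.
#' @export
reverse_complement <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  bad <- !(chars %in% DNA_ALPHABET)
  if (any(bad)) stop("illegal DNA character '", chars[which(bad)[1]], "'")
  paste(rev(unname(.complement[chars])), collapse = "")
}

#' @keywords internal
.translate_string <- function(dna) {
  L <- nchar(dna)
  if (L < 3) return("")
  ncod <- L %/% 3
  starts <- seq(1L, by = 3L, length.out = ncod)
  codons <- substring(dna, starts, starts + 2L)
  aa <- unname(.codon_table[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

#' Translate a DNA sequence in all six reading frames
#'
#' Frames +1/+2/+3 start at offsets 0/1/2 of the forward strand; frames
#' -1/-2/-3 at offsets 0/1/2 of the reverse complement. Trailing partial
#' codons are dropped, stop codons are rendered `*`, and any codon
#' containing N translates to X (even when the ambiguity is synonymous).
#' The standard genetic code (translation table 1) is used throughout.
#'
#' @param seq DNA string (length >= 3 for non-empty frames).
#' @return A list of six elements named `"+1" ... "-3"`, each with `frame`,
#'   `offset` (0-based, on the translated strand) and `peptide`.
#' @export
six_frame_translate <- function(seq) {
  L <- nchar(seq)
  if (L < 3) warning("sequence shorter than 3 nt: all frames empty")
  rc <- if (L > 0) reverse_complement(seq) else ""
  frames <- list()
  for (off in 0:2) {
    fwd <- if (L - off >= 3) substring(seq, off + 1, L) else ""
    rev <- if (L - off >= 3) substring(rc, off + 1, L) else ""
    frames[[paste0("+", off + 1)]] <-
      list(frame = paste0("+", off + 1), offset = off,
           peptide = .translate_string(fwd))
    frames[[paste0("-", off + 1)]] <-
      list(frame = paste0("-", off + 1), offset = off,
           peptide = .translate_string(rev))
  }
  frames[c("+1", "+2", "+3", "-1", "-2", "-3")]
}

#' Extract stop-to-stop open reading frames from all six frames
#'
#' ORFs are maximal stop-free stretches of the six-frame translation (no
#' start codon required) with peptide length at least `min_aa`. A stretch
#' must be closed by a stop codon in its frame; a stretch truncated by the
#' end of the sequence is an open reading that never terminates and is not
#' reported. Coordinates are reported on the forward strand, 0-based
#' half-open; for negative frames the slice must be reverse-complemented
#' before translation.
#'
#' @param seq DNA string or a record list with `id` and `residues`.
#' @param min_aa minimum peptide length (default 30).
#' @param genome_id label attached to each ORF.
#' @return A data.frame with columns `genome_id`, `frame`, `start`, `end`,
#'   `strand`, `length_aa`, `peptide`, ordered by frame (+1, +2, +3, -1,
#'   -2, -3) then forward-strand start.
#' @export
extract_orfs <- function(seq, min_aa = 30L, genome_id = "genome") {
  if (is.list(seq)) {
    genome_id <- seq$id %||% genome_id
    seq <- seq$residues
  }
  stopifnot(min_aa >= 1)
  L <- nchar(seq)
  frames <- six_frame_translate(seq)
  out <- list()
  for (fr in frames) {
    pep <- fr$peptide
    if (!nzchar(pep)) next
    m <- gregexpr("[^*]+", pep)[[1]]
    if (m[1] == -1) next
    lens <- attr(m, "match.length")
    # require a closing stop: the stretch must not run to the frame's end
    closed <- as.integer(m) + lens - 1L < nchar(pep)
    keep <- lens >= min_aa & closed
    if (!any(keep)) next
    a <- as.integer(m[keep]) - 1L      # 0-based peptide start within frame
    n <- as.integer(lens[keep])
    off <- fr$offset
    s_local <- off + 3L * a            # 0-based nt start on translated strand
    e_local <- s_local + 3L * n
    neg <- startsWith(fr$frame, "-")
    if (neg) {
      start <- L - e_local
      end <- L - s_local
    } else {
      start <- s_local
      end <- e_local
    }
    df <- data.frame(genome_id = genome_id, frame = fr$frame,
                     start = start, end = end,
                     strand = if (neg) "-" else "+",
                     length_aa = n,
                     peptide = substring(pep, a + 1L, a + n),
                     stringsAsFactors = FALSE)
    out[[fr$frame]] <- df[order(df$start), , drop = FALSE]
  }
  if (length(out) == 0) {
    return(data.frame(genome_id = character(), frame = character(),
                      start = integer(), end = integer(),
                      strand = character(), length_aa = integer(),
                      peptide = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write an ORF table as TSV (1-based inclusive coordinates)
#'
#' @param orfs data.frame from [extract_orfs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orf_table <- function(orfs, path) {
  tab <- data.frame(genome_id = orfs$genome_id, frame = orfs$frame,
                    start_1based = orfs$start + 1L, end_1based = orfs$end,
                    strand = orfs$strand, length_aa = orfs$length_aa,
                    peptide = orfs$peptide, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
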