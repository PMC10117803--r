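# Catalytic-residue conservation audits through a precomputed MSA.
# Structural alignment itself is out of scope: the package consumes
# aligned FASTA produced elsewhere.

#' Read a protein multiple sequence alignment (aligned FASTA)
#'
#' @param path aligned FASTA; rows must have equal length and use `-` for
#'   gaps.
#' @return An object of class `msa`: named character vector of aligned
#'   rows.
#' @export
read_msa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  idx <- cumsum(hdr)
  rows <- vapply(seq_len(sum(hdr)), function(k) {
    toupper(gsub("\\s", "", paste(lines[idx == k & !hdr], collapse = "")))
  }, character(1))
  names(rows) <- ids
  as_msa(rows)
}

#' Construct/validate an MSA object
#'
#' @param rows named character vector of equal-length aligned strings
#'   (residues plus `-`).
#' @return An object of class `msa`.
#' @export
as_msa <- function(rows) {
  if (length(rows) < 2) stop("an alignment needs at least 2 records")
  if (length(unique(nchar(rows))) != 1) {
    stop("aligned rows must have equal length")
  }
  bad <- grepl(paste0("[^-", paste(c(AA_ALPHABET20, "X"), collapse = ""),
                      "]"), rows)
  if (any(bad)) {
    stop("illegal character in aligned row '", names(rows)[bad][1], "'")
  }
  structure(rows, class = "msa")
}

#' Map ungapped reference positions to alignment columns
#'
#' Column k is chosen so that the number of non-gap reference characters
#' in columns 1..k equals the requested 1-based position.
#'
#' @param msa an [as_msa()] object.
#' @param reference_id row holding the reference sequence.
#' @param positions 1-based positions in the ungapped reference.
#' @return Integer vector of 0-based column indices.
#' @export
map_positions <- function(msa, reference_id, positions) {
  if (!reference_id %in% names(msa)) {
    stop("reference '", reference_id, "' not in alignment")
  }
  ref <- strsplit(unclass(msa)[[reference_id]], "")[[1]]
  cum <- cumsum(ref != "-")
  n <- cum[length(cum)]
  if (any(positions < 1 | positions > n)) {
    stop("position out of range 1..", n)
  }
  vapply(positions, function(p) which(cum == p)[1], integer(1)) - 1L
}

#' Define a catalytic-site specification
#'
#' @param reference_id reference sequence id.
#' @param sites data.frame with columns `position` (1-based, ungapped
#'   reference), `expected` (string of residues counted as conserved) and
#'   `loss` (string of residues flagged as loss-of-function). The two sets
#'   must be disjoint; conservative similarity (e.g. D vs E) is *not*
#'   treated as conserved unless listed.
#' @param name,provenance free-text labels (`provenance` records how the
#'   homology call was made, e.g. a remote-homology confidence level; it
#'   is metadata only and never recomputed).
#' @return An object of class `site_spec`.
#' @export
site_spec <- function(reference_id, sites, name = reference_id,
                      provenance = NULL) {
  stopifnot(all(c("position", "expected", "loss") %in% names(sites)))
  for (i in seq_len(nrow(sites))) {
    e <- strsplit(sites$expected[i], "")[[1]]
    l <- strsplit(sites$loss[i], "")[[1]]
    if (length(intersect(e, l)) > 0) {
      stop("expected and loss sets overlap at site ", i)
    }
  }
  structure(list(reference_id = reference_id, sites = sites, name = name,
                 provenance = provenance), class = "site_spec")
}

#' Load catalytic-site specifications from a YAML config
#'
#' @param path YAML file with a top-level `site_specs` list; each entry
#'   has `name`, `reference_id`, optional `provenance`, and `sites` with
#'   `position`, `expected`, `loss`.
#' @return Named list of [site_spec()] objects.
#' @export
load_site_specs <- function(path) {
  cfg <- yaml::read_yaml(path)
  specs <- lapply(cfg$site_specs, function(s) {
    sites <- do.call(rbind, lapply(s$sites, function(x) {
      data.frame(position = as.integer(x$position),
                 expected = as.character(x$expected),
                 loss = as.character(x$loss %||% ""),
                 stringsAsFactors = FALSE)
    }))
    site_spec(s$reference_id, sites, name = s$name %||% s$reference_id,
              provenance = s$provenance)
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Audit catalytic-site conservation across an alignment
#'
#' Every non-reference sequence gets one status per site: `conserved`
#' (observed residue in the expected set), `loss_flag` (in the loss set,
#' e.g. the aspartate-to-asparagine change that abolishes dehydratase
#' activity), `gap`, or `substituted` (anything else).
#'
#' @param msa an [as_msa()] object.
#' @param spec a [site_spec()].
#' @return An object of class `site_audit`: data.frame with `seq_id`,
#'   `site` (index), `position`, `column` (0-based), `observed`, `status`;
#'   attribute `summary` holds status counts.
#' @export
audit_sites <- function(msa, spec) {
  cols <- map_positions(msa, spec$reference_id, spec$sites$position)
  others <- setdiff(names(msa), spec$reference_id)
  rows <- list()
  for (sid in others) {
    chars <- strsplit(unclass(msa)[[sid]], "")[[1]]
    for (k in seq_along(cols)) {
      obs <- chars[cols[k] + 1L]
      expected <- strsplit(spec$sites$expected[k], "")[[1]]
      loss <- strsplit(spec$sites$loss[k], "")[[1]]
      status <- if (obs == "-") "gap"
        else if (obs %in% loss) "loss_flag"
        else if (obs %in% expected) "conserved"
        else "substituted"
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = sid, site = k, position = spec$sites$position[k],
        column = cols[k], observed = obs, status = status,
        stringsAsFactors = FALSE)
    }
  }
  rep <- do.call(rbind, rows)
  attr(rep, "summary") <- table(factor(
    rep$status, levels = c("conserved", "substituted", "loss_flag", "gap")))
  class(rep) <- c("site_audit", "data.frame")
  rep
}

#' Write a site-audit report as TSV
#'
#' @param report a [audit_sites()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_audit <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
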