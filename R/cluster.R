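# Glycogene cluster delineation from ordered gene annotations.

#' Functional classes counted as glyco-related by default
#'
#' Sugar-pathway and transfer enzymes flag a gene as glyco-related;
#' hypothetical, structural (GMC oxidoreductase) and unrelated classes do
#' not, but such genes can sit inside clusters via gap bridging, and the
#' flag can be overridden per gene.
#'
#' @return Character vector of class names mapped to `glyco_flag = TRUE`.
#' @export
glyco_classes <- function() {
  c("glycosyltransferase", "dehydratase", "aminotransferase",
    "acetyltransferase", "reductase", "epimerase", "methyltransferase",
    "pyruvyltransferase", "sulfotransferase", "sulfate_kinase")
}

#' Read a gene-annotation table
#'
#' TSV with columns `genome_id`, `gene_id`, `ordinal`, `functional_class`
#' and optional `glyco_flag_override` (TRUE/FALSE/empty). `glyco_flag` is
#' derived from `functional_class` via [glyco_classes()] unless overridden.
#'
#' @param path TSV path.
#' @return Annotation data.frame ordered by ordinal, with `glyco_flag`.
#' @export
read_annotations <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("genome_id", "gene_id", "ordinal", "functional_class")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) {
    stop("annotation file missing column(s): ", paste(miss, collapse = ", "))
  }
  annotate_genes(tab)
}

#' Derive glyco flags and validate an annotation table
#'
#' @param tab data.frame with `genome_id`, `gene_id`, `ordinal`,
#'   `functional_class` and optional `glyco_flag_override`.
#' @return The table ordered by ordinal with a logical `glyco_flag`.
#' @export
annotate_genes <- function(tab) {
  tab <- tab[order(tab$ordinal), , drop = FALSE]
  for (g in unique(tab$genome_id)) {
    o <- tab$ordinal[tab$genome_id == g]
    if (anyDuplicated(o) || any(diff(o) != 1)) {
      stop("ordinals must be unique and consecutive within genome '", g, "'")
    }
  }
  flag <- tab$functional_class %in% glyco_classes()
  if ("glyco_flag_override" %in% names(tab)) {
    ov <- tab$glyco_flag_override
    if (is.character(ov)) ov <- as.logical(ov)
    flag[!is.na(ov)] <- ov[!is.na(ov)]
  }
  tab$glyco_flag <- flag
  rownames(tab) <- NULL
  tab
}

#' Delineate glycogene clusters by contiguity with gap bridging
#'
#' Finds maximal runs of glyco-flagged genes in which interior runs of at
#' most `max_gap` non-glyco genes are bridged; clusters are trimmed so both
#' ends are glyco-flagged. Runs of a single gene are reported as
#' singletons. The default `max_gap = 3` equals the largest interior
#' non-glyco run observed inside a published Megavirinae cluster.
#'
#' @param annotations annotation data.frame (see [annotate_genes()]); must
#'   be ordered by ordinal.
#' @param max_gap maximum bridged interior run of non-glyco genes (>= 0).
#' @return A list with `clusters` and `singletons`, both data.frames with
#'   `genome_id`, `first_gene`, `last_gene`, `gene_count`, `members`
#'   (comma-separated gene ids in genome order).
#' @export
delineate_contiguous <- function(annotations, max_gap = 3L) {
  stopifnot(max_gap >= 0)
  if (is.unsorted(annotations$ordinal)) {
    stop("annotations must be ordered by ordinal")
  }
  out <- lapply(split(annotations, annotations$genome_id),
                .delineate_one, max_gap = max_gap)
  clusters <- do.call(rbind, lapply(out, `[[`, "clusters"))
  singletons <- do.call(rbind, lapply(out, `[[`, "singletons"))
  empty <- data.frame(genome_id = character(), first_gene = character(),
                      last_gene = character(), gene_count = integer(),
                      members = character(), stringsAsFactors = FALSE)
  list(clusters = if (is.null(clusters)) empty else
         `rownames<-`(clusters, NULL),
       singletons = if (is.null(singletons)) empty else
         `rownames<-`(singletons, NULL))
}

#' @keywords internal
.delineate_one <- function(ann, max_gap) {
  g <- which(ann$glyco_flag)
  rows <- list()
  if (length(g) > 0) {
    grp <- cumsum(c(1L, diff(g) - 1L > max_gap))
    for (k in unique(grp)) {
      idx <- g[grp == k]
      members <- ann$gene_id[idx[1]:idx[length(idx)]]
      rows[[k]] <- data.frame(
        genome_id = ann$genome_id[1],
        first_gene = members[1], last_gene = members[length(members)],
        gene_count = length(members),
        members = paste(members, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, rows)
  list(clusters = calls[calls$gene_count > 1, , drop = FALSE],
       singletons = calls[calls$gene_count == 1, , drop = FALSE])
}

#' Delineate the cluster region between two anchor genes
#'
#' Returns the genes lying strictly between a unique upstream anchor and a
#' unique downstream anchor (by functional class), the conserved
#' helicase / thioredoxin-like flanking arrangement of Megavirinae
#' glycogene regions. Anchor order in the genome does not matter.
#'
#' @param annotations annotation data.frame for one genome.
#' @param upstream_anchor_class,downstream_anchor_class functional-class
#'   labels occurring at most once each.
#' @return A one-row data.frame as in [delineate_contiguous()] (gene_count
#'   may be 0 for adjacent anchors), or `NULL` with a warning when either
#'   anchor is missing.
#' @export
delineate_by_anchors <- function(annotations, upstream_anchor_class,
                                 downstream_anchor_class) {
  if (length(unique(annotations$genome_id)) != 1) {
    stop("anchor delineation expects a single genome")
  }
  find <- function(cls) {
    hit <- which(annotations$functional_class == cls)
    if (length(hit) > 1) {
      stop("anchor class '", cls, "' occurs more than once: ",
           paste(annotations$gene_id[hit], collapse = ", "))
    }
    hit
  }
  up <- find(upstream_anchor_class)
  down <- find(downstream_anchor_class)
  if (length(up) == 0 || length(down) == 0) {
    warning("anchor class '",
            if (length(up) == 0) upstream_anchor_class else
              downstream_anchor_class,
            "' missing from genome '", annotations$genome_id[1], "'")
    return(NULL)
  }
  lo <- min(up, down)
  hi <- max(up, down)
  members <- if (hi - lo <= 1) character(0) else
    annotations$gene_id[(lo + 1):(hi - 1)]
  data.frame(genome_id = annotations$genome_id[1],
             first_gene = if (length(members)) members[1] else NA_character_,
             last_gene = if (length(members)) members[length(members)] else
               NA_character_,
             gene_count = length(members),
             members = paste(members, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Path to a packaged gene-annotation fixture
#'
#' Annotation tables transcribed from the published glycogene cluster
#' tables (with the flanking genes those reports name), for the genomes
#' `"mimivirus"`, `"moumouvirus_australiensis"`, `"moumouvirus_maliensis"`,
#' `"megavirus_chilensis"`, `"cotonvirus"` and `"tupanvirus_deep_ocean"`.
#'
#' @param genome fixture name.
#' @return File path under the package's `extdata`.
#' @export
annotation_fixture <- function(genome) {
  f <- system.file("extdata", paste0("annotations_", genome, ".tsv"),
                   package = "glycoscan")
  if (!nzchar(f)) stop("no packaged annotation fixture for '", genome, "'")
  f
}
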