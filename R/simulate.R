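# Synthetic genomes with implanted, diverged ortholog clusters and full
# ground truth, so every pipeline stage is testable without downloads.

# synonymous codons per amino acid (standard code), stops separate
.codons_by_aa <- local({
  tab <- Biostrings::GENETIC_CODE
  split(names(tab), unname(tab))
})
.stop_codons <- c("TAA", "TAG", "TGA")

# stop codons in all six frames on both strands (TTAA is revcomp-palindromic)
.orf_break <- "TTAATTAATTAA"

#' Mutate a peptide to a target amino-acid divergence
#'
#' Each position is independently substituted with probability
#' `divergence`; the replacement is drawn uniformly from the 19
#' non-identical standard residues. Substitutions are deliberately
#' uniform (not matrix-biased) so the divergence-score relationship stays
#' monotone and analyzable.
#'
#' @param peptide protein string over the 20 standard residues.
#' @param divergence substitution probability in \[0, 1\].
#' @return The mutated peptide.
#' @export
mutate_protein <- function(peptide, divergence) {
  stopifnot(divergence >= 0, divergence <= 1)
  chars <- strsplit(peptide, "")[[1]]
  hit <- runif(length(chars)) < divergence
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) {
      sample(setdiff(AA_ALPHABET20, a), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

#' Reverse-translate a peptide into a coding DNA sequence
#'
#' Synonymous codons are chosen uniformly; one stop codon (uniform over
#' TAA/TAG/TGA) is appended, so the output length is `3 * nchar(peptide)
#' + 3` and translating it round-trips to the peptide.
#'
#' @param peptide protein string over the 20 standard residues (X is an
#'   error: it has no codon).
#' @return DNA string.
#' @export
reverse_translate <- function(peptide) {
  chars <- strsplit(peptide, "")[[1]]
  if (any(chars == "X")) stop("cannot reverse-translate residue X")
  bad <- setdiff(unique(chars), AA_ALPHABET20)
  if (length(bad) > 0) stop("unknown residue '", bad[1], "'")
  codons <- vapply(chars, function(a) {
    opts <- .codons_by_aa[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1))
  paste(c(codons, .stop_codons[sample.int(3, 1)]), collapse = "")
}

#' Random intergenic DNA at a target GC fraction
#'
#' @param n length in bp.
#' @param gc GC fraction in (0, 1); G/C and A/T are split evenly.
#' @return DNA string.
#' @export
random_dna <- function(n, gc = 0.25) {
  if (n <= 0) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Simulation configuration for a synthetic genome
#'
#' @param seed integer seed; one seed drives all sampling in
#'   [build_genome()].
#' @param genome_length total length in bp.
#' @param intergenic_gc GC fraction of intergenic sequence (default 0.25,
#'   the AT-rich regime of the genomes this emulates).
#' @param cluster list describing the implanted cluster: `queries`
#'   (character vector of query ids, in implant order), `divergence`
#'   (per-gene, recycled), `strand` (per-gene, `"+"`/`"-"`, recycled),
#'   `interior_decoys` (count of non-glyco filler genes inserted between
#'   cluster genes).
#' @param decoy_orf_count random decoy genes placed outside the cluster.
#' @param catalytic_mutations list of lists with `gene`, `position`
#'   (1-based, ungapped), `to` (residue), applied after divergence.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed, genome_length, intergenic_gc = 0.25,
                       cluster = list(), decoy_orf_count = 0L,
                       catalytic_mutations = list()) {
  stopifnot(intergenic_gc > 0, intergenic_gc < 1, genome_length >= 3)
  if (length(cluster) > 0) {
    n <- length(cluster$queries)
    cluster$divergence <- rep(cluster$divergence %||% 0, length.out = n)
    cluster$strand <- rep(cluster$strand %||% "+", length.out = n)
    cluster$interior_decoys <- cluster$interior_decoys %||% 0L
    if (any(cluster$divergence < 0 | cluster$divergence > 1)) {
      stop("divergences must lie in [0, 1]")
    }
    if (!all(cluster$strand %in% c("+", "-"))) stop("strand must be + or -")
  }
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 intergenic_gc = intergenic_gc, cluster = cluster,
                 decoy_orf_count = as.integer(decoy_orf_count),
                 catalytic_mutations = catalytic_mutations),
            class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file mirroring the [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(sim_config, cfg)
}

#' Build a synthetic genome with an implanted ortholog cluster
#'
#' Cluster genes are reverse-translated copies of the query peptides,
#' mutated to the configured amino-acid divergence, laid out in order on
#' the configured strands with at least 50 bp of random intergenic
#' sequence between genes. Every implant is flanked by a short cassette
#' containing stop codons in all six frames so ORF extraction cannot fuse
#' adjacent genes. Decoy genes (random peptides of 30-80 aa) are placed
#' outside the cluster, and `interior_decoys` non-glyco fillers inside
#' it. Deterministic for a fixed seed.
#'
#' @param queries named character vector of query peptides (or records).
#' @param config a [sim_config()]; all its `cluster$queries` must be
#'   present in `queries`.
#' @param query_classes optional named character vector of functional
#'   classes for the annotation table (default `"glycosyltransferase"`).
#' @return A list of class `synthetic_genome`: `genome` (record with
#'   `id`, `residues`), `truth` (class `synthetic_truth`), `annotations`
#'   (data.frame compatible with [delineate_contiguous()]).
#' @export
build_genome <- function(queries, config, query_classes = NULL) {
  queries <- .as_records(queries)
  qmap <- setNames(vapply(queries, `[[`, character(1), "residues"),
                   vapply(queries, `[[`, character(1), "id"))
  set.seed(config$seed)
  cl <- config$cluster
  elements <- list()
  mutated <- list()

  if (length(cl) > 0) {
    miss <- setdiff(cl$queries, names(qmap))
    if (length(miss) > 0) stop("query '", miss[1], "' not supplied")
    for (k in seq_along(cl$queries)) {
      qid <- cl$queries[k]
      pep <- mutate_protein(qmap[[qid]], cl$divergence[k])
      muts <- Filter(function(m) m$gene == qid, config$catalytic_mutations)
      mrec <- list()
      for (m in muts) {
        chars <- strsplit(pep, "")[[1]]
        if (m$position > length(chars)) {
          stop("catalytic mutation position out of range for '", qid, "'")
        }
        mrec[[length(mrec) + 1L]] <- list(gene = qid,
                                          position = m$position,
                                          from = chars[m$position],
                                          to = m$to)
        chars[m$position] <- m$to
        pep <- paste(chars, collapse = "")
      }
      div_real <- mean(strsplit(pep, "")[[1]] !=
                         strsplit(qmap[[qid]], "")[[1]])
      elements[[length(elements) + 1L]] <- list(
        gene_id = qid, query_id = qid, peptide = pep,
        strand = cl$strand[k], in_cluster = TRUE, is_decoy = FALSE,
        divergence_requested = cl$divergence[k],
        divergence_realized = div_real, mutations = mrec,
        functional_class = if (!is.null(query_classes) &&
                               !is.na(query_classes[qid])) {
          unname(query_classes[qid])
        } else "glycosyltransferase")
      mutated[[qid]] <- pep
    }
    # interior decoys between randomly chosen adjacent cluster genes
    n_int <- cl$interior_decoys
    if (n_int > 0 && length(elements) > 1) {
      slots <- sort(sample(length(elements) - 1L, n_int, replace = TRUE))
      for (d in seq_len(n_int)) {
        pep <- paste(sample(AA_ALPHABET20, sample(30:80, 1),
                            replace = TRUE), collapse = "")
        el <- list(gene_id = sprintf("decoy_in_%02d", d), query_id = NA,
                   peptide = pep, strand = sample(c("+", "-"), 1),
                   in_cluster = FALSE, is_decoy = TRUE,
                   divergence_requested = NA, divergence_realized = NA,
                   mutations = list(), functional_class = "hypothetical")
        elements <- append(elements, list(el), after = slots[d] + (d - 1L))
      }
    }
  }

  # outside decoys: split before/after the cluster block
  n_out <- config$decoy_orf_count
  if (n_out > 0) {
    before <- if (length(elements) > 0) sample(0:n_out, 1) else n_out
    for (d in seq_len(n_out)) {
      pep <- paste(sample(AA_ALPHABET20, sample(30:80, 1),
                          replace = TRUE), collapse = "")
      el <- list(gene_id = sprintf("decoy_out_%02d", d), query_id = NA,
                 peptide = pep, strand = sample(c("+", "-"), 1),
                 in_cluster = FALSE, is_decoy = TRUE,
                 divergence_requested = NA, divergence_realized = NA,
                 mutations = list(), functional_class = "hypothetical")
      if (d <= before) {
        elements <- append(elements, list(el), after = d - 1L)
      } else {
        elements <- append(elements, list(el))
      }
    }
  }

  # assemble: [gap][brk cds brk][gap]...[gap], gaps >= 50 bp
  flank <- .orf_break
  cds_list <- lapply(elements, function(el) {
    cds <- reverse_translate(el$peptide)
    if (el$strand == "-") cds <- reverse_complement(cds)
    cds
  })
  elem_len <- vapply(cds_list, nchar, integer(1)) + 2L * nchar(flank)
  n_el <- length(elements)
  min_gap <- 50L
  need <- sum(elem_len) + min_gap * (n_el + 1L)
  if (need > config$genome_length) {
    stop("implants need ", need, " bp but genome_length is ",
         config$genome_length)
  }
  slack <- config$genome_length - need
  extra <- if (n_el >= 0 && slack > 0) {
    as.vector(stats::rmultinom(1, slack, rep(1, n_el + 1L)))
  } else rep(0L, n_el + 1L)
  gaps <- min_gap + extra

  pieces <- character(0)
  pos <- 0L
  truth_rows <- list()
  for (k in seq_len(n_el)) {
    gap <- random_dna(gaps[k], config$intergenic_gc)
    pieces <- c(pieces, gap, flank, cds_list[[k]], flank)
    cds_start <- pos + gaps[k] + nchar(flank)
    cds_end <- cds_start + nchar(cds_list[[k]])
    pos <- cds_end + nchar(flank)
    el <- elements[[k]]
    truth_rows[[k]] <- data.frame(
      gene_id = el$gene_id, query_id = el$query_id %||% NA_character_,
      start = cds_start, end = cds_end, strand = el$strand,
      divergence_requested = el$divergence_requested,
      divergence_realized = el$divergence_realized,
      peptide = el$peptide, in_cluster = el$in_cluster,
      is_decoy = el$is_decoy, functional_class = el$functional_class,
      stringsAsFactors = FALSE)
  }
  pieces <- c(pieces, random_dna(gaps[n_el + 1L], config$intergenic_gc))
  genome_seq <- paste(pieces, collapse = "")
  stopifnot(nchar(genome_seq) == config$genome_length)

  implants <- if (n_el > 0) do.call(rbind, truth_rows) else
    data.frame(gene_id = character(), query_id = character(),
               start = integer(), end = integer(), strand = character(),
               divergence_requested = numeric(),
               divergence_realized = numeric(), peptide = character(),
               in_cluster = logical(), is_decoy = logical(),
               functional_class = character(), stringsAsFactors = FALSE)
  cluster_members <- implants$gene_id[implants$in_cluster]
  mutations <- do.call(rbind, lapply(elements, function(el) {
    if (length(el$mutations) == 0) return(NULL)
    do.call(rbind, lapply(el$mutations, as.data.frame))
  }))

  gid <- sprintf("synthetic_%d", config$seed)
  ann <- data.frame(genome_id = rep(gid, nrow(implants)),
                    gene_id = implants$gene_id,
                    ordinal = seq_len(nrow(implants)),
                    functional_class = implants$functional_class,
                    stringsAsFactors = FALSE)
  ann <- annotate_genes(ann)

  truth <- structure(list(
    implants = implants,
    cluster_first = if (length(cluster_members)) cluster_members[1] else NA,
    cluster_last = if (length(cluster_members))
      cluster_members[length(cluster_members)] else NA,
    mutations = mutations, seed = config$seed), class = "synthetic_truth")
  structure(list(genome = list(id = gid, residues = genome_seq),
                 truth = truth, annotations = ann),
            class = "synthetic_genome")
}

#' Write a synthetic genome, its truth table and annotations to a directory
#'
#' @param sim result of [build_genome()].
#' @param dir output directory (created if needed): `genome.fna`,
#'   `truth.json`, `annotations.tsv`.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(list(sim$genome), file.path(dir, "genome.fna"))
  jsonlite::write_json(
    list(implants = sim$truth$implants,
         cluster_first = sim$truth$cluster_first,
         cluster_last = sim$truth$cluster_last,
         mutations = sim$truth$mutations, seed = sim$truth$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  write.table(sim$annotations, file.path(dir, "annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate a random peptide
#'
#' @param length peptide length.
#' @return Protein string over the 20 standard residues.
#' @export
random_peptide <- function(length) {
  paste(sample(AA_ALPHABET20, length, replace = TRUE), collapse = "")
}

#' Simulate a gene set at a target GC fraction
#'
#' @param n number of genes.
#' @param length gene length in bp.
#' @param gc target GC fraction.
#' @param prefix gene-id prefix.
#' @return Named character vector of DNA sequences.
#' @export
simulate_gene_set <- function(n, length, gc, prefix = "gene") {
  setNames(vapply(seq_len(n), function(i) random_dna(length, gc),
                  character(1)),
           sprintf("%s_%02d", prefix, seq_len(n)))
}

#' Simulate an error-free MSA around a reference with protected sites
#'
#' Generates `n` gapless homolog rows at the given divergence; positions
#' listed in `sites` keep the reference residue except in rows named by
#' `loss_rows`, where the site's loss residue is implanted. Used to
#' validate loss-of-function detection with known ground truth.
#'
#' @param reference reference peptide.
#' @param n number of homolog rows.
#' @param divergence per-position substitution probability elsewhere.
#' @param sites data.frame with `position` and `loss` (single residues).
#' @param loss_rows named list: homolog index -> vector of site indices
#'   carrying the loss substitution.
#' @param reference_id id of the reference row.
#' @return An `msa` with the reference first.
#' @export
simulate_msa <- function(reference, n, divergence, sites = NULL,
                         loss_rows = list(), reference_id = "ref") {
  refc <- strsplit(reference, "")[[1]]
  rows <- setNames(character(n), sprintf("seq_%02d", seq_len(n)))
  for (i in seq_len(n)) {
    chars <- strsplit(mutate_protein(reference, divergence), "")[[1]]
    if (!is.null(sites)) {
      chars[sites$position] <- refc[sites$position]
      li <- loss_rows[[as.character(i)]]
      if (!is.null(li)) {
        chars[sites$position[li]] <- vapply(sites$loss[li],
                                            function(s) substr(s, 1, 1),
                                            character(1))
      }
    }
    rows[i] <- paste(chars, collapse = "")
  }
  as_msa(c(setNames(reference, reference_id), rows))
}
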