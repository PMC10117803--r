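#!/usr/bin/env Rscript
# Calls nucleotide-sugar pathway completeness per panel genome from the
# conservation matrix, with the dead dehydratase copy marked impaired via
# the site audit. The clade-like repertoires should come out clade-like:
# e.g. the ctv1-like genome carries only the first two quinovosamine
# enzymes and is called partial.

suppressPackageStartupMessages(library(glycoscan))
stopifnot(file.exists("results/conservation_matrix.tsv"))

m <- import_matrix("results/conservation_matrix.tsv")
lib <- load_pathway_library(pathway_library_path())

# Audit the dehydratase catalytic aspartate in every genome's best Ma467
# hit: align the recovered ORF peptide under the reference (substitutions
# only in this panel, so columns map one-to-one) and check position 70.
queries <- read_fasta("results/panel/queries.faa", "protein")
ma467 <- Filter(function(r) r$id == "Ma467", queries)[[1]]
asp_spec <- site_spec("Ma467",
                      data.frame(position = 70, expected = "D",
                                 loss = "N"),
                      name = "pglf_catalytic_asp")
audit_rows <- list()
for (d in list.dirs("results/panel", recursive = FALSE)) {
  g <- read_fasta(file.path(d, "genome.fna"), "dna")[[1]]
  hit <- best_hit(ma467, extract_orfs(g$residues, genome_id = basename(d)))
  if (hit$conservation < 0.3) next
  pep <- hit$best_orf$peptide
  if (nchar(pep) != nchar(ma467$residues)) next
  rep <- audit_sites(as_msa(setNames(c(ma467$residues, pep),
                                     c("Ma467", "hit"))), asp_spec)
  audit_rows[[d]] <- data.frame(genome_id = basename(d),
                                site_spec = "pglf_catalytic_asp",
                                loss_flag = any(rep$status == "loss_flag"))
}
audits <- do.call(rbind, audit_rows)
cat("dehydratase aspartate lost in:",
    paste(audits$genome_id[audits$loss_flag], collapse = ", "), "\n")

all_calls <- list()
for (pw in lib) {
  present <- all(unlist(lapply(pw$steps, `[[`, "queries")) %in%
                   rownames(m$values))
  if (!present) next
  calls <- call_pathway(m, pw, threshold = 0.3, audits = audits)
  all_calls[[pw$name]] <- calls
  s <- summarize_pathway_calls(calls)
  cat(sprintf("%-20s %s\n", pw$name,
              paste(sprintf("%s:%s", s$genome_id, s$overall),
                    collapse = " ")))
}

tab <- do.call(rbind, all_calls)
rownames(tab) <- NULL
write.table(tab, "results/pathway_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(summarize_pathway_calls(tab),
                     "results/pathway_calls.json", auto_unbox = TRUE,
                     digits = NA)
cat("wrote results/pathway_calls.tsv and results/pathway_calls.json\n")
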