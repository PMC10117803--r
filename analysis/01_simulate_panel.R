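#!/usr/bin/env Rscript
# Builds the synthetic study panel: six genomes emulating clade-specific
# glycogene repertoires, each implanting a subset of reference enzymes
# (named after the packaged pathway library's query proteins) at realistic
# divergence, on an AT-rich background. Writes genomes, truth tables and
# the shared query set under results/panel/.

suppressPackageStartupMessages(library(glycoscan))
set.seed(2022)
out <- "results/panel"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# one synthetic reference protein per query id used by the pathway library
query_ids <- c("R141", "L780", "L136", "L142", "R132",      # Rha / Vio4NAc
               "L619", "L316", "R689",                      # GlcNAc
               "Mg534", "Mg535", "Mg536",                   # Qui2NAc
               "Ma458", "Ma459", "Ma460",
               "PglF", "PglE", "PglD",                      # diNAcBac refs
               "Ma467", "Ma465", "Ma466",
               "Mm422", "Mm421", "Mm419",                   # Qui2N/Fuc2N
               "R520")                                      # GlcA
queries <- setNames(vapply(query_ids, function(i) random_peptide(
  sample(150:300, 1)), character(1)), query_ids)
# the dehydratase reference carries its catalytic aspartate at position
# 70, so a loss-of-function copy can be implanted and audited downstream
queries["Ma467"] <- paste0(substr(queries[["Ma467"]], 1, 69), "D",
                           substr(queries[["Ma467"]], 71,
                                  nchar(queries[["Ma467"]])))
write_fasta(queries, file.path(out, "queries.faa"))

# clade-like repertoires: which enzymes each panel genome carries
design <- list(
  mimivirus_like = c("R141", "L780", "L136", "L142", "R132",
                     "L619", "L316", "R689"),
  australiensis_like = c("Ma458", "Ma459", "Ma460", "Ma467", "Ma465",
                         "Ma466", "L619", "L316", "R689"),
  maliensis_like = c("Mm422", "Mm421", "Mm419", "L619", "L316", "R689"),
  megavirus_like = c("Mg534", "Mg535", "Mg536", "L619", "L316", "R689"),
  ctv1_like = c("Mg534", "Mg535"),            # first two Qui2NAc enzymes
  tupanvirus_like = c("Ma467", "Ma465", "Ma466", "Mm422", "Mm421",
                      "R520", "L619", "L316", "R689"),
  # a B-clade strain whose dehydratase copy carries the dead aspartate
  monve_like = c("Ma467", "Ma465", "Ma466", "L619", "L316", "R689"))

for (i in seq_along(design)) {
  gname <- names(design)[i]
  implant <- design[[i]]
  cfg <- sim_config(
    seed = 3000 + i, genome_length = 30000, intergenic_gc = 0.25,
    cluster = list(queries = implant,
                   divergence = runif(length(implant), 0.05, 0.3),
                   strand = sample(c("+", "-"), length(implant),
                                   replace = TRUE)),
    decoy_orf_count = 5,
    catalytic_mutations = if (gname == "monve_like") {
      list(list(gene = "Ma467", position = 70, to = "N"))
    } else list())
  sim <- build_genome(queries, cfg)
  sim$genome$id <- gname
  dir.create(file.path(out, gname), showWarnings = FALSE)
  write_simulation(sim, file.path(out, gname))
  cat(sprintf("%-20s %2d implants, %5d bp, intergenic GC target 0.25\n",
              gname, length(implant), nchar(sim$genome$residues)))
}

writeLines(vapply(names(design), function(g) {
  paste(g, paste(design[[g]], collapse = ","), sep = "\t")
}, character(1)), file.path(out, "design.tsv"))
cat("panel written to", out, "\n")
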