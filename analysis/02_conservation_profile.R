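#!/usr/bin/env Rscript
# Translated search of the reference enzymes against every panel genome:
# builds the N x M conservation matrix (best ORF score / self-score),
# exports it as TSV and renders the clustered heatmap. Implanted enzymes
# should light up in their carrier genomes; absent ones should stay blue.

suppressPackageStartupMessages(library(glycoscan))
panel <- "results/panel"
stopifnot(dir.exists(panel))  # run analysis/01_simulate_panel.R first

recs <- read_fasta(file.path(panel, "queries.faa"), "protein")
genome_dirs <- list.dirs(panel, recursive = FALSE)
genomes <- lapply(genome_dirs, function(d) {
  g <- read_fasta(file.path(d, "genome.fna"), "dna")[[1]]
  g$id <- basename(d)
  g
})

m <- build_matrix(recs, genomes, min_score = 40, min_aa = 30)
export_matrix(m, "results/conservation_matrix.tsv")
render_heatmap(m, "results/conservation_heatmap.png",
               cluster_rows = TRUE, cluster_cols = TRUE)

v <- m$values
cat(sprintf("matrix: %d proteins x %d genomes; %d cells above 0.3\n",
            nrow(v), ncol(v), sum(v >= 0.3)))
design <- read.delim(file.path(panel, "design.tsv"), header = FALSE,
                     col.names = c("genome", "implants"))
for (i in seq_len(nrow(design))) {
  imp <- strsplit(design$implants[i], ",")[[1]]
  g <- design$genome[i]
  cat(sprintf("%-20s implanted detected %d/%d; max background %.3f\n", g,
              sum(v[imp, g] > 0.3), length(imp),
              max(v[setdiff(rownames(v), imp), g])))
}
cat("wrote results/conservation_matrix.tsv and results/conservation_heatmap.png\n")
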