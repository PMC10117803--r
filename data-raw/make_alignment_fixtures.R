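# Generates the packaged synthetic alignment fixtures under inst/extdata.
# The published alignment figures exist only as images, so these files are
# reconstructions: random backgrounds with exactly the stated residue
# correspondences preserved (MycE D275/H278/D304 <-> R132 D127/H138/D156;
# the dehydratase catalytic aspartate, position 396 of the PglF reference,
# conserved in functional orthologs and replaced by asparagine in
# gp464/mvR525/Mm419). Only those correspondences are asserted by tests.
# Run from the repository root: Rscript data-raw/make_alignment_fixtures.R

set.seed(20220406)
AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
        "F", "P", "S", "T", "W", "Y", "V")

rand_aa <- function(n) sample(AA, n, replace = TRUE)

mutate_keep <- function(chars, divergence, keep) {
  hit <- runif(length(chars)) < divergence
  hit[keep] <- FALSE
  chars[hit] <- vapply(chars[hit],
                       function(a) sample(setdiff(AA, a), 1), character(1))
  chars
}

write_afa <- function(rows, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(rows)) {
    writeLines(paste0(">", id), con)
    s <- rows[[id]]
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
}

## ---- MycE C-terminal methyltransferase domain vs R132 and A-clade rows

myce <- rand_aa(399)
myce[275] <- "D"; myce[278] <- "H"; myce[304] <- "D"
r132 <- rand_aa(221)
r132[127] <- "D"; r132[138] <- "H"; r132[156] <- "D"

# region table: (n columns, MycE consumed?, R132 consumed?)
regions <- rbind(c(148, 1, 0), c(126, 1, 1), c(1, 1, 1), c(2, 1, 1),
                 c(8, 0, 1), c(1, 1, 1), c(17, 1, 1), c(8, 1, 0),
                 c(1, 1, 1), c(65, 1, 1), c(30, 1, 0))

interleave <- function(ref, row, regions) {
  i <- 0L; j <- 0L
  ref_al <- character(0); row_al <- character(0)
  for (k in seq_len(nrow(regions))) {
    n <- regions[k, 1]
    if (regions[k, 2]) { ref_al <- c(ref_al, ref[i + seq_len(n)]); i <- i + n }
    else ref_al <- c(ref_al, rep("-", n))
    if (regions[k, 3]) { row_al <- c(row_al, row[j + seq_len(n)]); j <- j + n }
    else row_al <- c(row_al, rep("-", n))
  }
  list(ref = paste(ref_al, collapse = ""), row = paste(row_al, collapse = ""))
}

aln <- interleave(myce, r132, regions)
r132_sites <- c(127, 138, 156)
orth <- function() {
  paste(interleave(myce, mutate_keep(r132, 0.10, r132_sites),
                   regions)$row, collapse = "")
}
rows <- c(MycE = aln$ref, R132 = aln$row,
  R132_mamavirus = orth(), R132_hirudovirus = orth(), R132_bombay = orth())
write_afa(rows, "inst/extdata/myce_r132_synthetic_alignment.faa")

## ---- PglF-like dehydratase orthologs around the catalytic aspartate

pglf <- rand_aa(590)
pglf[396] <- "D"
slice <- pglf[313:590]          # the region the viral orthologs cover
site_local <- 396 - 312         # position of the aspartate in the slice

ortho_row <- function(divergence, loss) {
  chars <- mutate_keep(slice, divergence, site_local)
  chars[site_local] <- if (loss) "N" else "D"
  paste(c(rep("-", 312), chars), collapse = "")
}
rows2 <- c(
  PglF = paste(pglf, collapse = ""),
  Ma467 = ortho_row(0.30, FALSE),
  Cotonvirus_ORF_718 = ortho_row(0.30, FALSE),
  Tupanvirus_L515 = ortho_row(0.30, FALSE),
  Moumouvirus_gp464 = ortho_row(0.30, TRUE),
  Monve_mvR525 = ortho_row(0.30, TRUE),
  Mm419 = ortho_row(0.30, TRUE))
write_afa(rows2, "inst/extdata/pglf_orthologs_synthetic_alignment.faa")

cat("fixtures written\n")
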