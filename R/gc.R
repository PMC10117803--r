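# Per-gene GC fraction and glyco-vs-marker gene-set comparison.

#' GC fraction of a DNA sequence
#'
#' (#G + #C) / (#A + #C + #G + #T); N is excluded from both numerator and
#' denominator.
#'
#' @param seq DNA string or record with `residues`.
#' @return Fraction in \[0, 1\].
#' @export
gc_fraction <- function(seq) {
  if (is.list(seq)) seq <- seq$residues
  if (!nzchar(seq)) stop("empty sequence")
  chars <- strsplit(seq, "")[[1]]
  bad <- !(chars %in% DNA_ALPHABET)
  if (any(bad)) stop("illegal DNA character '", chars[which(bad)[1]], "'")
  n_gc <- sum(chars %in% c("G", "C"))
  n_acgt <- sum(chars != "N")
  if (n_acgt == 0) stop("sequence contains only N")
  n_gc / n_acgt
}

#' The seven core marker genes used as whole-genome GC representatives
#'
#' @return Character vector of marker-gene labels.
#' @export
marker_gene_set <- function() {
  c("Asp Synthase", "Helicase", "mRNA Capping Enzyme", "MutS",
    "Packaging ATPase", "PolyA polymerase", "VLTF3")
}

#' Compare GC content of glycogenes against marker genes
#'
#' Computes per-gene GC fractions, group means/SDs and their difference,
#' and a two-sided Mann-Whitney rank test (a quantitative surrogate for
#' the visual AT-richness comparison; labelled an extension of it). With
#' fewer than 2 genes in a group only descriptive statistics are
#' returned, with a warning.
#'
#' @param glyco_genes,marker_genes named character vectors of gene DNA
#'   sequences, or lists of records.
#' @return An object of class `gc_report`: `per_gene` data.frame
#'   (`gene_id`, `group`, `gc`), `summary` (means, sds, n, difference of
#'   means glyco - marker), `test` (statistic, p_value, method; NA when
#'   descriptive-only).
#' @export
compare_gene_sets <- function(glyco_genes, marker_genes) {
  gc_of <- function(x) {
    x <- .as_records(x)
    data.frame(gene_id = vapply(x, `[[`, character(1), "id"),
               gc = vapply(x, gc_fraction, numeric(1)),
               stringsAsFactors = FALSE)
  }
  if (length(glyco_genes) == 0 || length(marker_genes) == 0) {
    stop("both gene groups must be non-empty")
  }
  g <- gc_of(glyco_genes)
  m <- gc_of(marker_genes)
  per_gene <- rbind(cbind(g, group = "glyco"),
                    cbind(m, group = "marker"))
  summary <- list(mean_glyco = mean(g$gc), mean_marker = mean(m$gc),
                  sd_glyco = sd(g$gc), sd_marker = sd(m$gc),
                  n_glyco = nrow(g), n_marker = nrow(m),
                  diff_means = mean(g$gc) - mean(m$gc))
  test <- list(statistic = NA_real_, p_value = NA_real_,
               method = "descriptive only")
  if (nrow(g) < 2 || nrow(m) < 2) {
    warning("a group has fewer than 2 genes: descriptive-only report")
  } else {
    wt <- wilcox.test(g$gc, m$gc, alternative = "two.sided", exact = FALSE,
                      correct = TRUE)
    test <- list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 method = wt$method)
  }
  structure(list(per_gene = per_gene, summary = summary, test = test),
            class = "gc_report")
}

#' @export
print.gc_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "gc_report: glyco %.4f +/- %.4f (n=%d) vs marker %.4f +/- %.4f (n=%d)\n",
    s$mean_glyco, s$sd_glyco, s$n_glyco, s$mean_marker, s$sd_marker,
    s$n_marker))
  cat(sprintf("  diff of means %.4f; %s, p = %.4g\n", s$diff_means,
              x$test$method, x$test$p_value))
  invisible(x)
}
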