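test_that("published cluster fixtures delineate to their reported gene counts", {
  cases <- list(
    list(fix = "mimivirus", n = 12, first = "R132", last = "L143"),
    list(fix = "moumouvirus_australiensis", n = 12, first = "ma457",
         last = "ma468"),
    list(fix = "moumouvirus_maliensis", n = 6, first = "mm417",
         last = "mm422"),
    list(fix = "megavirus_chilensis", n = 6, first = "mg534",
         last = "mg539"),
    list(fix = "cotonvirus", n = 21, first = "ORF_708", last = "ORF_728"))
  for (cs in cases) {
    ann <- read_annotations(annotation_fixture(cs$fix))
    calls <- delineate_contiguous(ann, max_gap = 3)
    expect_equal(nrow(calls$clusters), 1, info = cs$fix)
    expect_equal(calls$clusters$gene_count, cs$n, info = cs$fix)
    expect_equal(calls$clusters$first_gene, cs$first, info = cs$fix)
    expect_equal(calls$clusters$last_gene, cs$last, info = cs$fix)
  }
})

test_that("anchor delineation returns genes strictly between unique anchors", {
  ann <- read_annotations(annotation_fixture("cotonvirus"))
  cl <- delineate_by_anchors(ann, "helicase", "thioredoxin_like")
  expect_equal(cl$gene_count, 7)
  expect_equal(strsplit(cl$members, ",")[[1]],
               paste0("ORF_", 708:714))

  # maliensis: the full six-gene cluster sits between the anchors
  ann2 <- read_annotations(annotation_fixture("moumouvirus_maliensis"))
  cl2 <- delineate_by_anchors(ann2, "helicase", "thioredoxin_like")
  expect_equal(cl2$gene_count, 6)
})

test_that("anchor delineation handles missing, duplicate and adjacent anchors", {
  ann <- annotate_genes(data.frame(
    genome_id = "t", gene_id = paste0("g", 1:4), ordinal = 1:4,
    functional_class = c("helicase", "thioredoxin_like",
                         "glycosyltransferase", "hypothetical")))
  expect_equal(delineate_by_anchors(ann, "helicase",
                                    "thioredoxin_like")$gene_count, 0)
  expect_warning(res <- delineate_by_anchors(ann, "helicase", "muts"),
                 "missing")
  expect_null(res)
  ann2 <- annotate_genes(data.frame(
    genome_id = "t", gene_id = paste0("g", 1:3), ordinal = 1:3,
    functional_class = c("helicase", "glycosyltransferase", "helicase")))
  expect_error(delineate_by_anchors(ann2, "helicase", "glycosyltransferase"),
               "more than once")
})

test_that("gap bridging trims cluster ends to glyco genes", {
  ann <- annotate_genes(data.frame(
    genome_id = "t", gene_id = paste0("g", 1:9), ordinal = 1:9,
    functional_class = c("hypothetical", "dehydratase", "hypothetical",
                         "hypothetical", "reductase", "hypothetical",
                         "hypothetical", "hypothetical",
                         "glycosyltransferase")))
  calls <- delineate_contiguous(ann, max_gap = 2)
  expect_equal(calls$clusters$members, "g2,g3,g4,g5")
  expect_equal(calls$singletons$members, "g9")

  none <- annotate_genes(data.frame(
    genome_id = "t", gene_id = paste0("g", 1:3), ordinal = 1:3,
    functional_class = rep("hypothetical", 3)))
  expect_equal(nrow(delineate_contiguous(none, 3)$clusters), 0)
  expect_equal(nrow(delineate_contiguous(none, 3)$singletons), 0)
})

test_that("delineation is invariant to reversing genome gene order", {
  ann <- read_annotations(annotation_fixture("cotonvirus"))
  rev_ann <- ann[rev(seq_len(nrow(ann))), ]
  rev_ann$ordinal <- seq_len(nrow(rev_ann))
  rev_ann <- annotate_genes(rev_ann)
  fwd <- delineate_contiguous(ann, 3)$clusters
  bwd <- delineate_contiguous(rev_ann, 3)$clusters
  expect_setequal(strsplit(fwd$members, ",")[[1]],
                  strsplit(bwd$members, ",")[[1]])
})

test_that("glyco flags come from the class map with per-gene overrides", {
  ann <- read_annotations(annotation_fixture("tupanvirus_deep_ocean"))
  # UDP-glucose 6-dehydrogenase: oxidoreductase class, overridden glyco
  expect_true(ann$glyco_flag[ann$gene_id == "R520"])
  expect_false(ann$glyco_flag[ann$gene_id == "R497"])
  expect_true(all(ann$glyco_flag[ann$functional_class %in% glyco_classes()]))
  expect_error(annotate_genes(data.frame(
    genome_id = "t", gene_id = c("a", "b"), ordinal = c(1, 3),
    functional_class = "other")), "consecutive")
})

test_that("implanted synthetic clusters are recovered with exact boundaries", {
  set.seed(19)
  q <- setNames(vapply(1:4, function(i) rand_pep(50), ""),
                paste0("gene", 1:4))
  for (seed in c(501, 502, 503)) {
    sim <- build_genome(q, sim_config(
      seed = seed, genome_length = 9000,
      cluster = list(queries = names(q), divergence = 0.2,
                     interior_decoys = 2),
      decoy_orf_count = 3))
    calls <- delineate_contiguous(sim$annotations, max_gap = 3)
    expect_equal(calls$clusters$first_gene, sim$truth$cluster_first)
    expect_equal(calls$clusters$last_gene, sim$truth$cluster_last)
  }
})
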