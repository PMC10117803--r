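test_that("local alignment reproduces hand-computed BLOSUM62 scores", {
  sch <- scoring_scheme()
  a <- sw_align("MKT", "MKT", sch)
  expect_equal(a$score, 15)  # diagonal entries M=5, K=5, T=5
  expect_equal(a$percent_identity, 100)
  expect_equal(a$query_coverage, 100)

  b <- sw_align("MKT", "PGW", sch)  # all nine pair scores negative
  expect_equal(b$score, 0)
  expect_equal(nrow(b$aligned_pairs), 0)

  expect_error(sw_align("", "MKT", sch), "non-empty")
})

test_that("self-score is the ungapped diagonal sum and matches self-alignment", {
  sch <- scoring_scheme()
  expect_equal(self_score("MKT", sch), 15)
  expect_equal(self_score("A", sch), 4)
  expect_error(self_score("M1T", sch), "absent")
  set.seed(3)
  for (k in 1:25) {
    q <- rand_pep(sample(5:60, 1))
    expect_equal(self_score(q, sch), sw_align(q, q, sch)$score)
  }
})

test_that("alignment scores agree with the brute-force DP oracle", {
  sch <- scoring_scheme()
  set.seed(101)
  for (k in 1:300) {
    q <- rand_pep(sample(1:8, 1))
    t <- rand_pep(sample(1:8, 1))
    expect_equal(sw_align(q, t, sch)$score, oracle_sw_score(q, t, sch))
  }
})

test_that("alignment scores agree with an established aligner on longer pairs", {
  sch <- scoring_scheme()
  data("BLOSUM62", package = "Biostrings", envir = environment())
  set.seed(55)
  for (k in 1:40) {
    q <- rand_pep(sample(15:60, 1))
    t <- rand_pep(sample(15:60, 1))
    ref <- Biostrings::pairwiseAlignment(
      q, t, type = "local", substitutionMatrix = BLOSUM62,
      gapOpening = sch$gap_open, gapExtension = sch$gap_extend,
      scoreOnly = TRUE)
    expect_equal(sw_align(q, t, sch)$score, max(0, ref))
  }
})

test_that("alignment score is symmetric under a symmetric scheme", {
  sch <- scoring_scheme()
  set.seed(77)
  for (k in 1:500) {
    q <- rand_pep(sample(3:30, 1))
    t <- rand_pep(sample(3:30, 1))
    expect_identical(sw_align(q, t, sch)$score, sw_align(t, q, sch)$score)
  }
})

test_that("identity and coverage statistics follow their definitions", {
  sch <- scoring_scheme()
  expect_equal(unname(pairwise_stats("MKTWQE", "MKTWQE", sch)), c(100, 100))
  # query whose first half matches the target exactly, second half absent
  set.seed(9)
  half <- rand_pep(20)
  query <- paste0(half, rand_pep(20))
  st <- pairwise_stats(query, half, sch)
  expect_equal(unname(st["query_coverage"]), 50)
  expect_equal(unname(st["percent_identity"]), 100)
})

test_that("best hit normalizes by self-score and applies the score floor", {
  sch <- scoring_scheme()
  set.seed(31)
  pep <- rand_pep(80)
  cds <- reverse_translate(pep)
  g <- paste0(random_dna(300, 0.3), "TTAATTAATTAA", cds, "TTAATTAATTAA",
              random_dna(300, 0.3))
  orfs <- extract_orfs(g, min_aa = 30, genome_id = "g1")
  e <- best_hit(list(id = "q", residues = pep), orfs, sch)
  expect_equal(e$conservation, 1)
  expect_equal(e$best_orf$peptide, pep)

  # unrelated query against a random genome: no hit above the floor
  g2 <- random_dna(20000, 0.25)
  orfs2 <- extract_orfs(g2, min_aa = 30, genome_id = "g2")
  e2 <- best_hit(list(id = "q2", residues = rand_pep(120)), orfs2, sch,
                 min_score = 50)
  expect_equal(e2$conservation, 0)
  expect_null(e2$best_orf)

  expect_warning(e3 <- best_hit("MKTW", orfs2[0, ], sch), "empty ORF")
  expect_equal(e3$conservation, 0)
})

test_that("a diverged ortholog scores between 0 and 1 and matches the oracle", {
  sch <- scoring_scheme()
  set.seed(13)
  q <- rand_pep(60)
  implant <- mutate_protein(q, 0.3)
  g <- paste0(random_dna(800, 0.3), "TTAATTAATTAA",
              reverse_translate(implant), "TTAATTAATTAA",
              random_dna(800, 0.3))
  orfs <- extract_orfs(g, min_aa = 20, genome_id = "g")
  e <- best_hit(list(id = "q", residues = q), orfs, sch, min_score = 20)
  expect_gt(e$conservation, 0)
  expect_lt(e$conservation, 1)
  oracle_best <- max(vapply(orfs$peptide, oracle_sw_score, numeric(1),
                            q = q, scheme = sch))
  expect_equal(e$best_score, oracle_best)
})

test_that("NCBI-format matrix files load into valid schemes", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# tiny demo matrix", "   A  C", "A  2 -1", "C -1  3"), f)
  m <- read_score_matrix(f)
  expect_equal(m["A", "A"], 2L)
  sch <- scoring_scheme(m, gap_open = 2, gap_extend = 1, name = "tiny")
  expect_true(sch$diagonal_dominant)
  expect_error(scoring_scheme(m, gap_open = 1, gap_extend = 2), "gap_extend")
})

test_that("the k-mer prefilter finds the same best hit as exact search", {
  sch <- scoring_scheme()
  set.seed(63)
  q <- rand_pep(100)
  g <- paste0(random_dna(3000, 0.3), "TTAATTAATTAA",
              reverse_translate(mutate_protein(q, 0.2)), "TTAATTAATTAA",
              random_dna(3000, 0.3))
  orfs <- extract_orfs(g, min_aa = 25, genome_id = "g")
  exact <- best_hit(list(id = "q", residues = q), orfs, sch)
  seeded <- best_hit(list(id = "q", residues = q), orfs, sch,
                     prefilter = TRUE)
  expect_equal(seeded$best_score, exact$best_score)
  expect_equal(seeded$best_orf$start, exact$best_orf$start)
})
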