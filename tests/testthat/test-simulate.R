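test_that("protein mutation hits the requested divergence", {
  set.seed(73)
  p <- rand_pep(200)
  expect_identical(mutate_protein(p, 0), p)
  m1 <- mutate_protein(p, 1)
  expect_true(all(strsplit(m1, "")[[1]] != strsplit(p, "")[[1]]))
  # realized substitutions within the exact binomial 99% interval
  p2 <- rand_pep(1000)
  m2 <- mutate_protein(p2, 0.3)
  nsub <- sum(strsplit(m2, "")[[1]] != strsplit(p2, "")[[1]])
  expect_gte(nsub, qbinom(0.005, 1000, 0.3))
  expect_lte(nsub, qbinom(0.995, 1000, 0.3))
})

test_that("reverse translation round-trips and appends one stop codon", {
  set.seed(79)
  for (k in 1:50) {
    p <- rand_pep(sample(5:80, 1))
    cds <- reverse_translate(p)
    expect_equal(nchar(cds), 3 * nchar(p) + 3)
    expect_identical(glycoscan:::.translate_string(cds), paste0(p, "*"))
  }
  expect_error(reverse_translate("MXK"), "X")
})

test_that("synonymous codons are drawn uniformly", {
  set.seed(83)
  cods <- vapply(1:3000, function(i) substr(reverse_translate("L"), 1, 3),
                 character(1))
  tab <- table(cods)
  expect_length(tab, 6)  # six leucine codons
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("genome building is deterministic and honors its length", {
  q <- c(gA = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
         gB = "WQNDLRETFLKEGMHVAPSYTTGSDE")
  cfg <- sim_config(seed = 97, genome_length = 4000,
                    cluster = list(queries = c("gA", "gB"),
                                   divergence = c(0.1, 0.3),
                                   strand = c("+", "-")),
                    decoy_orf_count = 2)
  s1 <- build_genome(q, cfg)
  s2 <- build_genome(q, cfg)
  expect_identical(s1$genome$residues, s2$genome$residues)
  expect_identical(s1$truth$implants, s2$truth$implants)
  expect_equal(nchar(s1$genome$residues), 4000)
})

test_that("truth-table CDS slices translate back to the realized peptides", {
  set.seed(89)
  q <- setNames(vapply(1:3, function(i) rand_pep(45), ""), paste0("q", 1:3))
  sim <- build_genome(q, sim_config(
    seed = 890, genome_length = 5000,
    cluster = list(queries = names(q), divergence = c(0, 0.2, 0.4),
                   strand = c("+", "-", "+"))))
  imp <- sim$truth$implants
  expect_equal(sum(!imp$is_decoy), 3)
  for (r in which(!imp$is_decoy)) {
    slice <- substring(sim$genome$residues, imp$start[r] + 1, imp$end[r])
    if (imp$strand[r] == "-") slice <- reverse_complement(slice)
    expect_identical(glycoscan:::.translate_string(slice),
                     paste0(imp$peptide[r], "*"))
  }
  # divergence-0 implant matches its query exactly
  expect_identical(imp$peptide[imp$query_id == "q1"], unname(q["q1"]))
})

test_that("intergenic sequence realizes the target GC fraction", {
  sim <- build_genome(character(0) |> setNames(character(0)),
                      sim_config(seed = 101, genome_length = 10000,
                                 intergenic_gc = 0.25))
  expect_equal(nchar(sim$genome$residues), 10000)
  expect_lt(abs(gc_fraction(sim$genome$residues) - 0.25), 0.03)
})

test_that("implants that cannot fit are rejected before generation", {
  q <- c(big = rand_pep(500))
  expect_error(build_genome(q, sim_config(
    seed = 1, genome_length = 1000, cluster = list(queries = "big"))),
    "genome_length")
})

test_that("catalytic point mutations are applied and recorded", {
  set.seed(103)
  q <- c(enz = paste0(rand_pep(20), "D", rand_pep(20)))
  sim <- build_genome(q, sim_config(
    seed = 104, genome_length = 3000,
    cluster = list(queries = "enz", divergence = 0),
    catalytic_mutations = list(list(gene = "enz", position = 21, to = "N"))))
  expect_equal(substr(sim$truth$implants$peptide[1], 21, 21), "N")
  expect_equal(sim$truth$mutations$from, "D")
  expect_equal(sim$truth$mutations$to, "N")
})

test_that("simulations write genome, truth and annotations to disk", {
  set.seed(107)
  q <- c(qa = rand_pep(40))
  sim <- build_genome(q, sim_config(seed = 108, genome_length = 2500,
                                    cluster = list(queries = "qa")))
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  expect_true(all(file.exists(file.path(
    d, c("genome.fna", "truth.json", "annotations.tsv")))))
  back <- read_fasta(file.path(d, "genome.fna"), "dna")
  expect_identical(back[[1]]$residues, sim$genome$residues)
  tr <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(tr$seed, 108)
})
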