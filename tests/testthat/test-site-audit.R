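fixture_msa <- function(name) {
  read_msa(system.file("extdata", name, package = "glycoscan"))
}

test_that("reference positions map through gaps to alignment columns", {
  msa <- as_msa(c(ref = "--MK-T", other = "AAMKTT"))
  expect_equal(map_positions(msa, "ref", 3), 5L)
  expect_equal(map_positions(msa, "ref", 1:2), c(2L, 3L))
  expect_error(map_positions(msa, "ref", 0), "range")
  expect_error(map_positions(msa, "ref", 4), "range")
  # ungapped reference: column is position - 1
  msa2 <- as_msa(c(ref = "MKTW", o = "MK-W"))
  expect_equal(map_positions(msa2, "ref", 1:4), 0:3)
})

test_that("methyltransferase catalytic residues are conserved across the A-clade rows", {
  msa <- fixture_msa("myce_r132_synthetic_alignment.faa")
  specs <- load_site_specs(system.file("extdata", "catalytic_sites.yaml",
                                       package = "glycoscan"))
  rep <- audit_sites(msa, specs$myce_methyltransferase)
  # the two Mg-coordinating aspartates and the 2-OH histidine
  for (sid in c("R132", "R132_mamavirus", "R132_hirudovirus",
                "R132_bombay")) {
    expect_equal(rep$status[rep$seq_id == sid], rep("conserved", 3),
                 info = sid)
  }
  # the alignment places them at R132 ungapped positions 127, 138, 156
  r132 <- gsub("-", "", unclass(msa)[["R132"]])
  cols <- map_positions(msa, "MycE", c(275, 278, 304))
  chars <- strsplit(unclass(msa)[["R132"]], "")[[1]]
  expect_equal(chars[cols + 1], c("D", "H", "D"))
  ungapped_pos <- vapply(cols, function(cl) {
    sum(strsplit(unclass(msa)[["R132"]], "")[[1]][seq_len(cl + 1)] != "-")
  }, integer(1))
  expect_equal(ungapped_pos, c(127L, 138L, 156L))
})

test_that("the dehydratase aspartate-to-asparagine loss is flagged in the fixture", {
  msa <- fixture_msa("pglf_orthologs_synthetic_alignment.faa")
  specs <- load_site_specs(system.file("extdata", "catalytic_sites.yaml",
                                       package = "glycoscan"))
  rep <- audit_sites(msa, specs$pglf_catalytic_asp)
  status <- setNames(rep$status, rep$seq_id)
  expect_equal(unname(status[c("Ma467", "Cotonvirus_ORF_718",
                               "Tupanvirus_L515")]), rep("conserved", 3))
  expect_equal(unname(status[c("Moumouvirus_gp464", "Monve_mvR525",
                               "Mm419")]), rep("loss_flag", 3))
})

test_that("audits classify gaps and implanted losses correctly", {
  set.seed(29)
  ref <- rand_pep(120)
  ref <- paste0(substr(ref, 1, 49), "D", substr(ref, 51, 120))
  sites <- data.frame(position = 50, expected = "D", loss = "N")
  msa <- simulate_msa(ref, n = 6, divergence = 0.2, sites = sites,
                      loss_rows = list(`2` = 1), reference_id = "ref")
  spec <- site_spec("ref", sites)
  rep <- audit_sites(msa, spec)
  expect_equal(rep$status[rep$seq_id == "seq_02"], "loss_flag")
  expect_equal(sum(rep$status == "loss_flag"), 1)

  # gap across the site column
  rows <- unclass(msa)
  chars <- strsplit(rows[["seq_03"]], "")[[1]]
  chars[50] <- "-"
  rows[["seq_03"]] <- paste(chars, collapse = "")
  rep2 <- audit_sites(as_msa(rows), spec)
  expect_equal(rep2$status[rep2$seq_id == "seq_03"], "gap")
})

test_that("inserting gap-only columns never changes a status", {
  set.seed(37)
  ref <- paste0(rand_pep(30), "D", rand_pep(30), "H", rand_pep(30))
  sites <- data.frame(position = c(31, 62), expected = c("D", "H"),
                      loss = c("N", ""))
  msa <- simulate_msa(ref, n = 5, divergence = 0.25, sites = sites,
                      loss_rows = list(`4` = 1), reference_id = "ref")
  spec <- site_spec("ref", sites)
  base <- audit_sites(msa, spec)
  for (k in 1:20) {
    at <- sample(nchar(unclass(msa)[[1]]) + 1, 1)
    rows <- vapply(unclass(msa), function(s) {
      paste0(substr(s, 1, at - 1), "-", substr(s, at, nchar(s)))
    }, character(1))
    shifted <- audit_sites(as_msa(rows), spec)
    expect_equal(shifted$status, base$status)
    expect_equal(shifted$observed, base$observed)
  }
})

test_that("site specs reject overlapping expected and loss sets", {
  expect_error(site_spec("r", data.frame(position = 1, expected = "D",
                                         loss = "DN")), "overlap")
})
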