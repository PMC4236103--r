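test_that("single-nucleotide neighbors are the 9 one-off codons", {
  expect_setequal(singleNtNeighbors("ATG"),
                  c("TTG", "CTG", "GTG", "AAG", "ACG", "AGG",
                    "ATA", "ATC", "ATT"))
  expect_setequal(singleNtNeighbors("AAA"),
                  c("CAA", "GAA", "TAA", "ACA", "AGA", "ATA",
                    "AAC", "AAG", "AAT"))
  ## every codon has exactly 9 neighbors, none equal to itself
  codons <- apply(expand.grid(c("A", "C", "G", "T"),
                              c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste,
                  collapse = "")
  for (cd in sample(codons, 12)) {
    nb <- singleNtNeighbors(cd)
    expect_length(nb, 9)
    expect_false(cd %in% nb)
  }
  expect_error(singleNtNeighbors("AT"), "3 bases")
  expect_error(singleNtNeighbors("ATN"), "invalid DNA")
})

test_that("accessible amino-acid changes drop synonymous and stops", {
  ## frozen values computed with an independent translate-all-neighbors
  ## oracle (Biostrings::translate)
  expect_setequal(accessibleAaChanges("ATG"),
                  c("L", "V", "K", "T", "R", "I"))
  expect_setequal(accessibleAaChanges("TGG"),
                  c("R", "G", "S", "L", "C"))
  expect_setequal(accessibleAaChanges("CTG"),
                  c("M", "V", "Q", "P", "R"))
  expect_error(accessibleAaChanges("TAA"), "stop codon")
  ## RNA input is canonicalized
  expect_identical(accessibleAaChanges("AUG"), accessibleAaChanges("ATG"))
})

test_that("enumeration over a toy CDS gives the per-codon union", {
  acc <- enumerateAccessible("ATGGCATGG", removeInitialMet = TRUE)
  expect_identical(nrow(acc), 11L)
  expect_setequal(acc$aa_to[acc$site == 1],
                  c("P", "S", "T", "E", "G", "V"))
  expect_setequal(acc$aa_to[acc$site == 2],
                  c("R", "G", "S", "L", "C"))
  expect_identical(unique(acc$aa_from[acc$site == 1]), "A")
  ## terminal stop codon tolerated, internal stop rejected
  expect_identical(enumerateAccessible("ATGGCATGGTAA"), acc)
  expect_error(enumerateAccessible("ATGTAATGG"), "internal stop")
  expect_error(enumerateAccessible("ATGGCATG"), "multiple of 3")
  expect_error(enumerateAccessible("GCATGG", removeInitialMet = TRUE),
               "begin with ATG")
})

test_that("all-substitution enumeration yields 19 keys per residue", {
  expect_identical(nrow(enumerateAll("AW")), 38L)
  expect_identical(nrow(enumerateAll("")), 0L)
  a <- enumerateAll("C")
  expect_false("C" %in% a$aa_to)
  expect_error(enumerateAll("AXB"), "invalid residue")
})

test_that("accessible enumeration agrees with a brute-force point-mutant
           oracle on random CDSs", {
  set.seed(101)
  for (rep in 1:8) {
    cds <- randomCds(sample(10:90, 1))
    got <- enumerateAccessible(cds, removeInitialMet = TRUE)
    want <- bruteForceAccessible(cds, removeInitialMet = TRUE)
    expect_identical(got[order(got$site, got$aa_to), ], want)
    ## accessible is a subset of all, at most 9 per site
    all <- enumerateAll(translateCds(cds, removeInitialMet = TRUE))
    expect_true(all(paste(got$site, got$aa_to) %in%
                      paste(all$site, all$aa_to)))
    expect_true(all(table(got$site) <= 9))
  }
  ## determinism
  cds <- randomCds(40)
  expect_identical(enumerateAccessible(cds), enumerateAccessible(cds))
})

test_that("CDS reading handles FASTA and GenBank flat files", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">geneF toy", "ATGGCATGG"), fa)
  expect_identical(readCds(fa), "ATGGCATGG")

  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TOY                 18 bp    DNA     linear",
    "FEATURES             Location/Qualifiers",
    "     source          1..18",
    "     CDS             4..12",
    "                     /gene=\"F\"",
    "ORIGIN",
    "        1 aaaatggcat ggcccttt",
    "//"), gb)
  expect_identical(readCds(gb, gene = "F"), "ATGGCATGG")
  expect_error(readCds(gb, gene = "G"), "no CDS feature")
})
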