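test_that("cysteine sanitisation replaces every C and nothing else", {
  expect_identical(sanitize_peptide("ACDEFC"), "AADEFA")
  expect_identical(sanitize_peptide("MKLV"), "MKLV")
  expect_identical(sanitize_peptide("CCCC"), "AAAA")
  expect_error(sanitize_peptide("ACDXF"), "position 4")
})

test_that("tiling covers an interior variant with the expected windows", {
  d <- mini_design() # 30-residue region, SNV at position 15, len 16 step 4
  expect_identical(sort(d$window_start), c(1L, 5L, 9L, 13L))
  expect_equal(nrow(d), 4)
  # every pair differs at exactly one residue, at the variant position
  for (i in seq_len(nrow(d))) {
    wt <- strsplit(d$wt_peptide[i], "")[[1]]
    mut <- strsplit(d$mut_peptide[i], "")[[1]]
    diffs <- which(wt != mut)
    expect_length(diffs, 1)
    expect_identical(d$window_start[i] + diffs - 1L, d$position[i])
  }
})

test_that("two variants in one window share the wild-type peptide", {
  seq <- mini_region()$sequence
  vars <- dplyr::bind_rows(
    mini_variant(position = 14, mut = "W"),
    mini_variant(position = 16, mut = "M")
  )
  d <- tile_region(mini_region(), vars)
  shared <- dplyr::distinct(dplyr::filter(d, window_start == 13), wt_peptide)
  expect_equal(nrow(shared), 1)
  expect_equal(
    nrow(dplyr::filter(d, window_start == 13)), 2
  ) # one mutant peptide per variant
})

test_that("a region shorter than the peptide length yields no pairs", {
  r <- mini_region()
  r$end <- 10L
  r$sequence <- substr(r$sequence, 1, 10)
  expect_warning(
    d <- tile_region(r, mini_variant(position = 5)),
    "shorter than peptide_len"
  )
  expect_equal(nrow(d), 0)
})

test_that("terminal variants are rescued by an anchored end window", {
  seq <- mini_region()$sequence # 30 residues; grid windows end at 28
  d <- tile_region(mini_region(), mini_variant(position = 30))
  expect_equal(nrow(d), 1)
  expect_identical(d$window_start, 15L) # anchored to the region end
})

test_that("variants contradicting the region sequence are rejected", {
  expect_error(
    tile_region(mini_region(), mini_variant(position = 15, wt = "Y")),
    "P1:15"
  )
  expect_error(
    tile_region(mini_region(), mini_variant(position = 99, wt = "A")),
    "outside region"
  )
})

test_that("interior variants are covered by at least three windows", {
  # coverage property at len 16 / step 4 for positions away from the ends
  set.seed(401)
  seq <- paste0(sample(setdiff(c("A", "D", "E", "H", "K"), NULL), 60,
                       replace = TRUE), collapse = "")
  r <- list(protein_id = "P1", start = 1L, end = 60L, sequence = seq)
  for (pos in 13:48) {
    d <- tile_region(r, mini_variant(position = pos, seq = seq))
    expect_gte(nrow(d), 3)
    expect_lte(nrow(d), 4) # ceil(16 / 4)
  }
})

test_that("reverse translation round-trips and avoids the forbidden site", {
  set.seed(402)
  for (i in 1:25) {
    pep <- paste0(sample(setdiff(AA <- c("A", "D", "E", "F", "G", "H", "I",
                                         "K", "L", "M", "N", "P", "Q", "R",
                                         "S", "T", "V", "W", "Y"), NULL),
                         16, replace = TRUE), collapse = "")
    dna <- reverse_translate(pep)
    back <- as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                               no.init.codon = TRUE))
    expect_identical(back, pep)
    expect_false(grepl("CCCGGG", dna, fixed = TRUE))
  }
  expect_identical(reverse_translate("M"), "ATG")
})

test_that("forbidden-site avoidance backtracks at junctions", {
  # a usage table whose top-ranked codons would spell CCCGGG across the
  # P|G junction forces the fallback codon
  usage <- ecoli_codon_table()
  usage$P <- c("CCC", "CCG")
  usage$G <- c("GGG", "GGC")
  dna <- reverse_translate("PG", codon_usage = usage)
  expect_false(grepl("CCCGGG", dna, fixed = TRUE))
  expect_identical(
    as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                       no.init.codon = TRUE)), "PG"
  )
})

test_that("design summary deduplicates peptides and mutations", {
  d <- mini_design()
  s <- summarize_design(d)
  expect_equal(s$n_mutations, 1)
  expect_equal(s$n_pairs, 4)
  expect_equal(s$n_wt_peptides, 4)
  expect_equal(s$n_unique_peptides, 8)
  # one shared wt serving two mutants is still one wt peptide
  vars <- dplyr::bind_rows(
    mini_variant(position = 14, mut = "W"),
    mini_variant(position = 16, mut = "M")
  )
  d2 <- tile_region(mini_region(), vars)
  s2 <- summarize_design(d2)
  expect_equal(s2$n_mutations, 2)
  expect_lt(s2$n_wt_peptides, s2$n_pairs)
})

test_that("summary percentages are computed on unique mutations", {
  d <- tibble::tibble(
    protein_id = "P1",
    position = 1:10, wt_aa = "A", mut_aa = "V",
    mutation = paste0("A", 1:10, "V"),
    window_start = 1L,
    wt_peptide = paste0("PEP", 1:10), mut_peptide = paste0("MUT", 1:10),
    pathogenicity = rep(c("pathogenic", "other"), c(7, 3)),
    origin = rep(c("somatic", "germline"), c(4, 6)),
    disease_categories = c(rep("cancer", 5), rep("cancer;metabolic", 5))
  )
  s <- summarize_design(d)
  expect_equal(s$pct_pathogenic, 70.0)
  expect_equal(s$pct_somatic, 40.0)
  expect_equal(s$disease_category_counts[[1]][["mixed"]], 5L)
  expect_equal(s$disease_category_counts[[1]][["cancer"]], 5L)
})

test_that("design_library attaches valid oligos for every pair", {
  lib <- simulate_library(sim_config(seed = 3, n_per_class = 1))
  d <- design_library(lib$regions, lib$variants)
  expect_gt(nrow(d), 0)
  for (col in c("wt_oligo", "mut_oligo")) {
    pep_col <- sub("_oligo", "_peptide", col)
    back <- vapply(d[[col]], function(x) {
      as.character(Biostrings::translate(Biostrings::DNAString(x),
                                         no.init.codon = TRUE))
    }, character(1), USE.NAMES = FALSE)
    expect_identical(back, d[[pep_col]])
    expect_false(any(grepl("CCCGGG", d[[col]], fixed = TRUE)))
    expect_false(any(grepl("C", d[[pep_col]], fixed = TRUE)))
  }
})
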