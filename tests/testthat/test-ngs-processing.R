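make_reads <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- vapply(nchar(seqs), strrep, character(1), x = "I")
  tibble::tibble(
    read_id = sprintf("r%03d", seq_along(seqs)), seq = seqs, qual = quals
  )
}

test_that("dual-barcode demultiplexing requires both barcodes to match", {
  scheme <- tibble::tibble(
    sample_id = c("A", "B"),
    barcode5 = c("AAAA", "CCCC"), barcode3 = c("TTTT", "GGGG"),
    bait_id = "B1", replicate = c(1L, 2L), day = 1L
  )
  reads <- make_reads(c(
    "AAAAGGATCGTTTT",  # A's pair -> A
    "AAAAGGATCGGGGG",  # A's 5' with B's 3' -> unassigned
    "CCCCGGATCGGGGG"   # B's pair -> B
  ))
  out <- suppressMessages(demultiplex(reads, scheme))
  expect_identical(out$sample_id, c("A", NA, "B"))
  expect_identical(out$replicate, c(1L, NA, 2L))
})

test_that("demultiplexing an empty read set returns an empty table", {
  scheme <- tibble::tibble(sample_id = "A", barcode5 = "AAAA", barcode3 = "TTTT")
  out <- demultiplex(make_reads(character(0)), scheme)
  expect_equal(nrow(out), 0)
  expect_true("sample_id" %in% names(out))
})

test_that("duplicate barcode pairs are a configuration error", {
  scheme <- tibble::tibble(
    sample_id = c("A", "B"),
    barcode5 = c("AAAA", "AAAA"), barcode3 = c("TTTT", "TTTT")
  )
  expect_error(demultiplex(make_reads("AAAATTTT"), scheme), "Ambiguous")
})

test_that("quality filtering uses a strict less-than rule on the mean", {
  # Phred+33: "4" = 19, "5" = 20, "I" = 40
  reads <- make_reads(
    c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAC"),
    c(
      paste0(strrep("5", 9), "4"),  # mean 19.9 -> discard
      strrep("5", 10),              # mean 20.0 -> keep
      strrep("I", 10)               # mean 40   -> keep
    )
  )
  kept <- quality_filter(reads, min_avg_q = 20)
  expect_identical(kept$read_id, c("r002", "r003"))
  bad <- make_reads("ACGT", "III")
  expect_error(quality_filter(bad), "length mismatch")
})

test_that("insert translation round-trips with the design and rejects are labelled", {
  design_pep <- c("MKL", "PGA")
  a5 <- "GGTGGA"
  a3 <- "GGAAGC"
  mk <- function(insert) paste0(a5, insert, a3)
  reads <- make_reads(c(
    mk(reverse_translate("PGA")),        # designed peptide
    mk("ATGTAACTG"),                     # internal stop codon
    mk(reverse_translate("WWW")),        # valid peptide, not designed
    mk("AT"),                            # broken frame
    paste0("TTTT", reverse_translate("PGA"), "TTTT") # no adapters
  ))
  out <- trim_translate_match(reads, a5, a3, design_pep)
  expect_identical(out$peptide[1], "PGA")
  expect_identical(
    out$reject_reason[2:5],
    c("frame/stop", "not-in-design", "frame/stop", "no-adapter")
  )
})

test_that("singleton cleaning removes exactly the count-of-one entries", {
  counts <- tibble::tibble(
    bait_id = "B1", peptide = c("P1", "P2", "P3"),
    replicate = 1L, day = c(3L, 3L, 3L), count = c(1L, 2L, 10L)
  )
  cleaned <- clean_counts(counts)
  expect_identical(cleaned$peptide, c("P2", "P3"))
  expect_equal(nrow(clean_counts(counts[0, ])), 0)
})

test_that("normalisation sums to the scale within each day", {
  counts <- tibble::tibble(
    bait_id = "B1",
    peptide = rep(c("P1", "P2", "P3"), 2),
    replicate = 1L,
    day = rep(1:2, each = 3),
    count = c(100L, 300L, 600L, 5L, 5L, 10L)
  )
  norm <- normalise_counts(counts, scale = 1e6)
  sums <- dplyr::summarise(
    dplyr::group_by(norm, day), s = sum(norm_count)
  )
  expect_equal(sums$s, c(1e6, 1e6))
})

test_that("day merging averages with zero-fill over sequenced days", {
  # peptide present on day 4 only (normalised 50), two sequenced days
  counts <- tibble::tibble(
    bait_id = "B1",
    peptide = c("P1", "P2", "P2"),
    replicate = 1L,
    day = c(4L, 4L, 3L),
    count = c(50L, 950L, 100L)
  )
  merged <- normalise_and_merge(counts, scale = 1000)
  p1 <- merged$merged_count[merged$peptide == "P1"]
  expect_equal(p1, 25) # (50 + 0) / 2
  merged_obs <- normalise_and_merge(counts, scale = 1000, zero_fill = FALSE)
  expect_equal(merged_obs$merged_count[merged_obs$peptide == "P1"], 50)
})

test_that("read conservation holds through counting", {
  cfg <- sim_config(seed = 17, n_per_class = 1, depth = 200,
                    n_replicates = 2, n_days = 2)
  lib <- simulate_library(cfg)
  des <- design_library(lib$regions, lib$variants)
  sim <- simulate_counts(des, cfg, emit = "fastq")
  res <- suppressMessages(count_reads(
    sim$reads, sim$scheme, sim$adapter5, sim$adapter3,
    c(des$wt_peptide, des$mut_peptide)
  ))
  f <- res$read_fates
  expect_equal(
    f$unassigned + f$low_quality + f$rejected_no_adapter +
      f$rejected_frame_stop + f$rejected_not_in_design + f$counted,
    f$input
  )
  # simulated reads are clean, so the counts reproduce the simulated table
  expect_equal(sum(res$counts$count), sum(sim$counts$count))
  joined <- dplyr::full_join(
    res$counts, sim$counts,
    by = c("bait_id", "peptide", "replicate", "day"),
    suffix = c("_obs", "_sim")
  )
  expect_equal(joined$count_obs, joined$count_sim)
})

test_that("identical FASTQ input produces bit-identical count tables", {
  cfg <- sim_config(seed = 19, n_per_class = 1, depth = 100,
                    n_replicates = 2, n_days = 1)
  lib <- simulate_library(cfg)
  des <- design_library(lib$regions, lib$variants)
  sim <- simulate_counts(des, cfg, emit = "fastq")
  run <- function() suppressMessages(count_reads(
    sim$reads, sim$scheme, sim$adapter5, sim$adapter3,
    c(des$wt_peptide, des$mut_peptide)
  ))$counts
  expect_identical(run(), run())
})

test_that("FASTQ writing and reading round-trip", {
  reads <- make_reads(c("ACGTACGT", "GGGGCCCC"))
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_identical(back$seq, reads$seq)
  expect_identical(back$qual, reads$qual)
})
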