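# Processing of amplicon sequencing reads from phage selections into
# per-bait, per-replicate, per-selection-day peptide count tables. Reads
# carry dual barcodes flanking adapter-delimited peptide-coding inserts:
#   [barcode5][adapter5][insert][adapter3][barcode3]
# Inserts are translated in the fixed phagemid frame and retained only when
# the peptide matches the library design.

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ file (gzip-aware via the underlying reader).
#' @return tibble with `read_id`, `seq` and `qual` (Phred+33 string).
#' @export
read_fastq <- function(path) {
  # the reader emits a benign note about dropped metadata columns
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  tibble(
    read_id = sub("\\s.*$", "", names(x)),
    seq = unname(as.character(x)),
    qual = unname(as.character(Biostrings::quality(x)))
  )
}

#' Write a read tibble to FASTQ
#'
#' @param reads tibble with `read_id`, `seq`, `qual`.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id)),
    Biostrings::PhredQuality(reads$qual)
  )
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Average Phred quality of each read
#'
#' @param qual character vector of Phred+33 quality strings.
#' @return numeric vector of arithmetic mean per-base scores.
#' @export
mean_quality <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q) - 33L), numeric(1), USE.NAMES = FALSE)
}

#' Discard reads below an average quality threshold
#'
#' A read is discarded iff the arithmetic mean of its per-base Phred scores
#' is strictly below `min_avg_q`; a read at exactly the threshold is kept.
#'
#' @param reads read tibble (see [read_fastq()]).
#' @param min_avg_q minimum average Phred score.
#' @return the retained reads.
#' @export
quality_filter <- function(reads, min_avg_q = 20) {
  bad <- nchar(reads$seq) != nchar(reads$qual)
  if (any(bad)) {
    abort(sprintf(
      "Malformed record: sequence/quality length mismatch for read '%s'",
      reads$read_id[which(bad)[1]]
    ))
  }
  reads[mean_quality(reads$qual) >= min_avg_q, , drop = FALSE]
}

#' Assign reads to samples by their 5' and 3' barcodes
#'
#' Both barcodes must match exactly (dual-barcode rule): a read carrying
#' sample A's 5' barcode but sample B's 3' barcode stays unassigned.
#'
#' @param reads read tibble.
#' @param scheme tibble with one row per sample: `sample_id`, `barcode5`,
#'   `barcode3`, plus any sample metadata columns (e.g. `bait_id`,
#'   `replicate`, `day`) which are carried through.
#' @return `reads` with the scheme columns joined on; unassigned reads have
#'   `sample_id` `NA`. The number of unassigned reads is reported.
#' @export
demultiplex <- function(reads, scheme) {
  stopifnot(nrow(scheme) > 0)
  if (anyDuplicated(scheme[, c("barcode5", "barcode3")])) {
    abort("Ambiguous barcode scheme: duplicate (barcode5, barcode3) pair")
  }
  hit_id <- rep(NA_integer_, nrow(reads))
  for (i in seq_len(nrow(scheme))) {
    b5 <- scheme$barcode5[i]
    b3 <- scheme$barcode3[i]
    ok <- startsWith(reads$seq, b5) & endsWith(reads$seq, b3) &
      nchar(reads$seq) >= nchar(b5) + nchar(b3)
    hit_id[ok & !is.na(hit_id)] <- -1L # matched by >1 sample: unassigned
    hit_id[ok & is.na(hit_id)] <- i
  }
  hit_id[!is.na(hit_id) & hit_id < 0] <- NA_integer_
  out <- reads
  for (col in setdiff(names(scheme), names(reads))) {
    out[[col]] <- scheme[[col]][hit_id]
  }
  n_un <- sum(is.na(hit_id))
  if (n_un > 0) {
    message(sprintf("demultiplex: %d of %d reads unassigned", n_un, nrow(reads)))
  }
  out
}

#' Trim adapters, translate inserts and match against the design
#'
#' For each assigned read the insert between `adapter5` and `adapter3`
#' (after stripping the sample barcodes) is translated in the fixed frame.
#' Rejections are data, not errors: each read gets either a `peptide` or a
#' `reject_reason` of "no-adapter" (adapters not found in order),
#' "frame/stop" (insert length not a multiple of three, or an internal stop
#' codon) or "not-in-design" (valid peptide absent from the library design).
#'
#' @param reads demultiplexed read tibble (non-`NA` `sample_id`).
#' @param adapter5,adapter3 constant adapter sequences flanking the insert.
#' @param design_peptides character vector of designed peptides (the union
#'   of wild-type and mutant peptides).
#' @return `reads` with `peptide` and `reject_reason` columns.
#' @export
trim_translate_match <- function(reads, adapter5, adapter3, design_peptides) {
  design_set <- unique(design_peptides)
  peptide <- rep(NA_character_, nrow(reads))
  reason <- rep(NA_character_, nrow(reads))
  for (i in seq_len(nrow(reads))) {
    s <- reads$seq[i]
    if ("barcode5" %in% names(reads) && !is.na(reads$barcode5[i])) {
      s <- substr(s, nchar(reads$barcode5[i]) + 1,
                  nchar(s) - nchar(reads$barcode3[i]))
    }
    p5 <- regexpr(adapter5, s, fixed = TRUE)[1]
    p3 <- regexpr(adapter3, s, fixed = TRUE)[1]
    ins_start <- p5 + nchar(adapter5)
    if (p5 < 0 || p3 < 0 || p3 < ins_start) {
      reason[i] <- "no-adapter"
      next
    }
    insert <- substr(s, ins_start, p3 - 1)
    if (nchar(insert) == 0 || nchar(insert) %% 3 != 0) {
      reason[i] <- "frame/stop"
      next
    }
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(insert), no.init.codon = TRUE
    ))
    if (grepl("*", aa, fixed = TRUE)) {
      reason[i] <- "frame/stop"
      next
    }
    if (!aa %in% design_set) {
      reason[i] <- "not-in-design"
      next
    }
    peptide[i] <- aa
  }
  out <- reads
  out$peptide <- peptide
  out$reject_reason <- reason
  out
}

#' Full read-to-counts pipeline for one FASTQ pool
#'
#' Demultiplexes, quality-filters, trims/translates/matches and tallies
#' peptide counts per sample. Sample metadata columns from the scheme
#' (`bait_id`, `replicate`, `day`) label the count table.
#'
#' @inheritParams demultiplex
#' @inheritParams trim_translate_match
#' @inheritParams quality_filter
#' @return list with `counts` (tibble `bait_id`, `peptide`, `replicate`,
#'   `day`, `count`) and `read_fates` (tally of assigned / discarded /
#'   rejected / counted reads).
#' @export
count_reads <- function(reads, scheme, adapter5, adapter3, design_peptides,
                        min_avg_q = 20) {
  n_in <- nrow(reads)
  reads <- demultiplex(reads, scheme)
  assigned <- reads[!is.na(reads$sample_id), , drop = FALSE]
  kept <- quality_filter(assigned, min_avg_q = min_avg_q)
  matched <- trim_translate_match(kept, adapter5, adapter3, design_peptides)
  ok <- matched[!is.na(matched$peptide), , drop = FALSE]
  counts <- ok %>%
    dplyr::count(
      dplyr::across(dplyr::any_of(c("bait_id", "replicate", "day"))),
      .data$peptide, name = "count"
    ) %>%
    dplyr::relocate(dplyr::any_of(c("bait_id", "peptide", "replicate", "day")))
  fates <- tibble(
    input = n_in,
    unassigned = n_in - nrow(assigned),
    low_quality = nrow(assigned) - nrow(kept),
    rejected_no_adapter = sum(matched$reject_reason == "no-adapter", na.rm = TRUE),
    rejected_frame_stop = sum(matched$reject_reason == "frame/stop", na.rm = TRUE),
    rejected_not_in_design = sum(matched$reject_reason == "not-in-design", na.rm = TRUE),
    counted = nrow(ok)
  )
  list(counts = counts, read_fates = fates)
}

#' Remove singleton counts
#'
#' Within each (bait, replicate, day) a peptide observed exactly once is
#' treated as carry-over noise and removed; counts of two or more are kept.
#'
#' @param counts count tibble (`bait_id`, `peptide`, `replicate`, `day`,
#'   `count`).
#' @return the cleaned count tibble.
#' @export
clean_counts <- function(counts) {
  dplyr::filter(counts, .data$count != 1)
}

#' Normalise counts within each selection day
#'
#' Raw counts are scaled to `scale` (counts-per-million by default) within
#' each (bait, replicate, day) over the retained peptides. Days with a zero
#' total are excluded with a warning. Downstream scores are built on
#' within-day count fractions, so the choice of `scale` cancels.
#'
#' @inheritParams clean_counts
#' @param scale normalisation constant per (replicate, day).
#' @return count tibble with a `norm_count` column.
#' @export
normalise_counts <- function(counts, scale = 1e6) {
  grouped <- counts %>%
    dplyr::group_by(dplyr::across(dplyr::any_of(c("bait_id", "replicate", "day"))))
  totals <- grouped %>% dplyr::summarise(total = sum(.data$count), .groups = "drop")
  zero <- totals[totals$total == 0, , drop = FALSE]
  if (nrow(zero) > 0) {
    warn(sprintf("%d selection day(s) with zero total count excluded", nrow(zero)))
  }
  grouped %>%
    dplyr::mutate(norm_count = .data$count * .env$scale / sum(.data$count)) %>%
    dplyr::ungroup() %>%
    dplyr::filter(is.finite(.data$norm_count))
}

#' Normalise per day and merge selection days per replicate
#'
#' Selection days of one replicate are merged into a per-peptide normalised
#' average count: the arithmetic mean of the day-normalised counts over the
#' days that replicate was sequenced, with absent (peptide, day)
#' combinations counted as zero by default.
#'
#' @inheritParams normalise_counts
#' @param zero_fill if `TRUE` (default) a peptide missing on a sequenced day
#'   contributes zero to the average; if `FALSE` the mean runs over the days
#'   the peptide was observed.
#' @return tibble `bait_id`, `peptide`, `replicate`, `merged_count`.
#' @export
normalise_and_merge <- function(counts, scale = 1e6, zero_fill = TRUE) {
  norm <- normalise_counts(counts, scale = scale)
  days_per_rep <- norm %>%
    dplyr::distinct(
      dplyr::across(dplyr::any_of(c("bait_id", "replicate"))), .data$day
    ) %>%
    dplyr::count(
      dplyr::across(dplyr::any_of(c("bait_id", "replicate"))), name = "n_days"
    )
  merged <- norm %>%
    dplyr::group_by(
      dplyr::across(dplyr::any_of(c("bait_id", "peptide", "replicate")))
    ) %>%
    dplyr::summarise(
      sum_norm = sum(.data$norm_count),
      n_obs_days = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::left_join(days_per_rep, by = intersect(
      c("bait_id", "replicate"), names(days_per_rep)
    ))
  merged %>%
    dplyr::mutate(
      merged_count = .data$sum_norm /
        (if (zero_fill) .data$n_days else .data$n_obs_days)
    ) %>%
    dplyr::select(dplyr::any_of(c("bait_id", "peptide", "replicate", "merged_count")))
}
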