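# Motif consensus mapping: locate a bait's short-linear-motif consensus in
# the sequence window around each mutation and classify the mutation's
# position as key (constrained consensus position), wild-card (unconstrained
# position inside a match), flanking (match elsewhere in the window),
# motif-created (the consensus exists only in the mutant sequence and the
# mutated residue sits at a constrained position) or no-motif.

#' Parse a motif consensus pattern
#'
#' Supports an ELM-style subset: plain residues (fixed), bracketed residue
#' classes like `[FILV]` (fixed), and `x` or `.` wild-cards.
#'
#' @param consensus consensus string, e.g. `"[FILV]xFG"`, `"PPxY"`.
#' @return list with `allowed` (list of residue vectors, `NULL` for
#'   wild-cards), `fixed` (logical per position) and `length`.
#' @export
parse_motif <- function(consensus) {
  stopifnot(is.character(consensus), length(consensus) == 1, nzchar(consensus))
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  allowed <- list()
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)[1]
      if (is.na(close)) abort(sprintf("Unclosed '[' in consensus '%s'", consensus))
      allowed[[length(allowed) + 1]] <- chars[(i + 1):(close - 1)]
      i <- close + 1
    } else if (ch %in% c("x", ".")) {
      allowed[length(allowed) + 1] <- list(NULL)
      i <- i + 1
    } else if (ch %in% AA_CANONICAL) {
      allowed[[length(allowed) + 1]] <- ch
      i <- i + 1
    } else {
      abort(sprintf("Unsupported character '%s' in consensus '%s'", ch, consensus))
    }
  }
  if (length(allowed) < 2) abort("Consensus must have at least 2 positions")
  list(
    allowed = allowed,
    fixed = !vapply(allowed, is.null, logical(1)),
    length = length(allowed)
  )
}

#' Find all matches of a consensus in a sequence window
#'
#' @param window amino-acid string.
#' @param motif consensus string or result of [parse_motif()].
#' @return tibble with `start` and `end` (1-based, inclusive) of every
#'   (possibly overlapping) match.
#' @export
scan_motif <- function(window, motif) {
  if (is.character(motif)) motif <- parse_motif(motif)
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  m <- motif$length
  starts <- integer(0)
  if (length(chars) >= m) {
    for (s in seq_len(length(chars) - m + 1)) {
      ok <- TRUE
      for (j in seq_len(m)) {
        a <- motif$allowed[[j]]
        if (!is.null(a) && !chars[s + j - 1] %in% a) {
          ok <- FALSE
          break
        }
      }
      if (ok) starts <- c(starts, s)
    }
  }
  tibble(start = starts, end = starts + m - 1)
}

#' Extract the sequence window around a mutation
#'
#' Returns the wild-type and mutant versions of the `flank`-residue window
#' centred on the mutation, truncated at the protein termini.
#'
#' @param protein_seq full-length protein sequence.
#' @param position 1-based residue position of the substitution start.
#' @param wt_aa,mut_aa substituted residues (equal-length strings; single
#'   characters for SNVs).
#' @param flank number of residues on each side of the mutation.
#' @return list with `wt_window`, `mut_window`, `window_start` (absolute
#'   coordinate of the first window residue) and `mut_offset` (position of
#'   the substitution start inside the window).
#' @export
extract_window <- function(protein_seq, position, wt_aa, mut_aa, flank = 20) {
  n <- nchar(protein_seq)
  span <- nchar(wt_aa)
  stopifnot(nchar(mut_aa) == span)
  if (position < 1 || position + span - 1 > n) {
    abort(sprintf("Position %d outside protein of length %d", position, n))
  }
  found <- substr(protein_seq, position, position + span - 1)
  if (found != wt_aa) {
    abort(sprintf(
      "Expected wild-type '%s' at position %d but found '%s'",
      wt_aa, position, found
    ))
  }
  w_start <- max(1, position - flank)
  w_end <- min(n, position + span - 1 + flank)
  wt_window <- substr(protein_seq, w_start, w_end)
  off <- position - w_start + 1
  mut_window <- paste0(
    substr(wt_window, 1, off - 1), mut_aa,
    substr(wt_window, off + span, nchar(wt_window))
  )
  list(
    wt_window = wt_window, mut_window = mut_window,
    window_start = w_start, mut_offset = off
  )
}

#' Classify a mutation's position relative to a motif consensus
#'
#' Both windows are scanned for consensus matches. A wild-type match
#' covering the mutated position yields `key` (constrained position) or
#' `wildcard`; a match covering the position only in the mutant window,
#' with the mutated residue at a constrained position, yields
#' `motif_created`; matches only away from the position yield `flanking`
#' with the nearest-match distance; no match in either window yields
#' `no_motif`. Ties between overlapping matches are broken toward the match
#' covering the mutation, then leftmost. Curated instances supplied via
#' `known_matches` take precedence over de novo scanning.
#'
#' @param wt_window,mut_window windows from [extract_window()].
#' @param pos position of the substitution start inside the window
#'   (`mut_offset` from [extract_window()]).
#' @param motif consensus string or parsed motif.
#' @param known_matches optional tibble of curated instances (`start`,
#'   `end`, window coordinates) used instead of scanning the wild-type
#'   window.
#' @return one-row tibble: `category`, `motif_start`, `motif_end`,
#'   `distance_to_motif`.
#' @export
classify_mutation <- function(wt_window, mut_window, pos, motif,
                              known_matches = NULL) {
  if (is.character(motif)) motif <- parse_motif(motif)
  span <- nchar(wt_window) - nchar(mut_window) # 0 for equal-length substitution
  stopifnot(span == 0)
  mut_positions <- which(
    strsplit(wt_window, "")[[1]] != strsplit(mut_window, "")[[1]]
  )
  if (length(mut_positions) == 0) mut_positions <- pos
  covers <- function(m) {
    m$start <= max(mut_positions) & m$end >= min(mut_positions)
  }
  wt_m <- if (!is.null(known_matches) && nrow(known_matches) > 0) {
    tibble(start = known_matches$start, end = known_matches$end)
  } else {
    scan_motif(wt_window, motif)
  }
  mut_m <- scan_motif(mut_window, motif)

  annotate <- function(category, mstart, mend, dist) {
    tibble(
      category = factor(category, levels = c(
        "key", "wildcard", "flanking", "motif_created", "no_motif"
      )),
      motif_start = mstart, motif_end = mend, distance_to_motif = dist
    )
  }

  wt_cover <- wt_m[covers(wt_m), , drop = FALSE]
  if (nrow(wt_cover) > 0) {
    hit <- wt_cover[order(wt_cover$start), ][1, ]
    in_motif <- mut_positions - hit$start + 1
    in_motif <- in_motif[in_motif >= 1 & in_motif <= motif$length]
    is_key <- any(motif$fixed[in_motif])
    return(annotate(
      if (is_key) "key" else "wildcard", hit$start, hit$end, 0
    ))
  }
  mut_cover <- mut_m[covers(mut_m), , drop = FALSE]
  if (nrow(mut_cover) > 0) {
    # creation requires the mutated residue at a constrained position
    for (r in seq_len(nrow(mut_cover))) {
      hit <- mut_cover[r, ]
      in_motif <- mut_positions - hit$start + 1
      in_motif <- in_motif[in_motif >= 1 & in_motif <= motif$length]
      if (any(motif$fixed[in_motif])) {
        return(annotate("motif_created", hit$start, hit$end, 0))
      }
    }
  }
  away <- if (!is.null(known_matches) && nrow(known_matches) > 0) {
    wt_m # curated instances take precedence over de novo scanning
  } else {
    dplyr::distinct(dplyr::bind_rows(wt_m, mut_m))
  }
  if (nrow(away) > 0) {
    d <- pmax(
      away$start - max(mut_positions),
      min(mut_positions) - away$end
    )
    d <- pmax(d, 0)
    best <- which(d == min(d))
    best <- best[order(away$start[best])][1]
    return(annotate("flanking", away$start[best], away$end[best], d[best]))
  }
  annotate("no_motif", NA_integer_, NA_integer_, NA_integer_)
}

#' Annotate one mutation against a bait's motif model
#'
#' Convenience wrapper combining [extract_window()], [classify_mutation()]
#' and the Grantham distance ([grantham()]). For multi-residue
#' substitutions the Grantham columns are `NA`.
#'
#' @inheritParams extract_window
#' @inheritParams classify_mutation
#' @param bait_id,protein_id identifiers carried into the output.
#' @return one-row tibble: identifiers, `mutation`, `category`,
#'   `motif_start`/`motif_end` (absolute coordinates), `distance_to_motif`,
#'   `grantham`, `grantham_class`.
#' @export
annotate_mutation <- function(protein_seq, position, wt_aa, mut_aa, motif,
                              bait_id = NA_character_,
                              protein_id = NA_character_,
                              flank = 20, known_matches = NULL) {
  w <- extract_window(protein_seq, position, wt_aa, mut_aa, flank = flank)
  cls <- classify_mutation(
    w$wt_window, w$mut_window, w$mut_offset, motif,
    known_matches = known_matches
  )
  g <- if (nchar(wt_aa) == 1) grantham(wt_aa, mut_aa) else NA_real_
  tibble(
    bait_id = bait_id,
    protein_id = protein_id,
    mutation = paste0(wt_aa, position, mut_aa),
    category = cls$category,
    motif_start = cls$motif_start + w$window_start - 1L,
    motif_end = cls$motif_end + w$window_start - 1L,
    distance_to_motif = cls$distance_to_motif,
    grantham = g,
    grantham_class = if (is.na(g)) factor(NA, levels = levels(grantham_class(0))) else grantham_class(g)
  )
}

#' Scan a window with a position-specific scoring matrix
#'
#' Optional alternative to the consensus scan: sums per-position log-odds
#' weights at every offset and reports spans scoring at or above the
#' threshold.
#'
#' @param window amino-acid string.
#' @param pssm numeric matrix, rows = motif positions, columns named by the
#'   20 residues, entries log-odds weights.
#' @param threshold minimum total score for a match.
#' @return tibble with `start`, `end`, `score` per match.
#' @export
pssm_scan <- function(window, pssm, threshold) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  m <- nrow(pssm)
  out <- list()
  if (length(chars) >= m) {
    for (s in seq_len(length(chars) - m + 1)) {
      ci <- match(chars[s:(s + m - 1)], colnames(pssm))
      if (anyNA(ci)) next
      sc <- sum(pssm[cbind(seq_len(m), ci)])
      if (sc >= threshold) {
        out[[length(out) + 1]] <- tibble(start = s, end = s + m - 1, score = sc)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(start = integer(), end = integer(), score = numeric()))
  }
  dplyr::bind_rows(out)
}
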