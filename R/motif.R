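#' Default conserved motif-block definitions for purple acid phosphatases
#'
#' The five conserved motif blocks of the metallophosphoesterase catalytic
#' domain, D-x-G / G-D-x-x-Y / G-N-H-\[DE\] / V-x-x-H / G-H-x-H, carrying the
#' seven metal-ligating residues (D, D, Y, N, H, H, H) that coordinate the
#' binuclear Fe-Zn/Fe-Mn center. `x` matches any of the 20 canonical
#' residues (never a gap or stop); `[..]` is a residue set. The ligand
#' flag in block 3 sits on the N only. The single tolerated substitution
#' shipped by default is the terminal Y -> F of block 2, the one variant
#' documented in known plant PAP families; users can extend the list.
#'
#' @param blocks optional replacement definitions; a list of lists with
#'   elements `block_index`, `pattern`, `ligand_mask`, and optionally
#'   `substitutions` (a named list mapping position to allowed alternative
#'   residues).
#' @return a list of `MotifBlockDef` entries (class `pap_blocks`), each
#'   with `block_index`, `positions` (list of residue sets), `ligand_flags`
#'   (logical), `tolerated_substitutions`, `pattern`.
#' @examples
#' defs <- pap_block_defs()
#' length(defs) # 5 blocks
#' sum(vapply(defs, function(b) sum(b$ligand_flags), integer(1))) # 7 ligands
#' @export
pap_block_defs <- function(blocks = NULL) {
  if (is.null(blocks)) {
    blocks <- list(
      list(block_index = 1L, pattern = "DxG",
           ligand_mask = c(TRUE, FALSE, FALSE)),
      list(block_index = 2L, pattern = "GDxxY",
           ligand_mask = c(FALSE, TRUE, FALSE, FALSE, TRUE),
           substitutions = list("5" = "F")),
      list(block_index = 3L, pattern = "GNH[DE]",
           ligand_mask = c(FALSE, TRUE, FALSE, FALSE)),
      list(block_index = 4L, pattern = "VxxH",
           ligand_mask = c(FALSE, FALSE, FALSE, TRUE)),
      list(block_index = 5L, pattern = "GHxH",
           ligand_mask = c(FALSE, TRUE, FALSE, TRUE))
    )
  }
  defs <- lapply(blocks, function(b) {
    pos <- parse_block_pattern(b$pattern)
    if (length(b$ligand_mask) != length(pos)) {
      stop("ligand_mask length must equal pattern length for block ",
           b$block_index, call. = FALSE)
    }
    subs <- lapply(b$substitutions %||% list(), function(s) chars(toupper(paste(s, collapse = ""))))
    structure(
      list(
        block_index = as.integer(b$block_index),
        pattern = b$pattern,
        positions = pos,
        ligand_flags = as.logical(b$ligand_mask),
        tolerated_substitutions = subs
      ),
      class = "MotifBlockDef"
    )
  })
  idx <- vapply(defs, `[[`, integer(1), "block_index")
  if (is.unsorted(idx, strictly = TRUE)) {
    stop("block definitions must be ordered by block_index", call. = FALSE)
  }
  structure(defs, class = "pap_blocks")
}

## "GNH[DE]" -> list of residue-set character vectors; "x"/"X" = wildcard.
parse_block_pattern <- function(pattern) {
  toks <- regmatches(pattern, gregexpr("\\[[A-Za-z/]+\\]|[A-Za-z]", pattern))[[1]]
  if (paste(toks, collapse = "") != pattern) {
    stop("cannot parse block pattern '", pattern, "'", call. = FALSE)
  }
  lapply(toks, function(tk) {
    if (startsWith(tk, "[")) {
      set <- chars(toupper(gsub("[][/]", "", tk)))
      bad <- setdiff(set, AA)
      if (length(bad)) stop("invalid residue '", bad[1], "' in pattern", call. = FALSE)
      set
    } else if (toupper(tk) == "X") {
      AA
    } else {
      r <- toupper(tk)
      if (!r %in% AA) stop("invalid residue '", r, "' in pattern", call. = FALSE)
      r
    }
  })
}

## All raw matches of one block on a sequence, with optional tolerated
## substitutions (at most one substituted position per match is reported;
## exact matches are preferred at the same start).
raw_block_matches <- function(seq_chars, def, allow_substitutions = TRUE) {
  L <- length(def$positions)
  n <- length(seq_chars)
  out <- list()
  if (n < L) return(out)
  for (s in seq_len(n - L + 1L)) {
    word <- seq_chars[s:(s + L - 1L)]
    mism <- unname(which(!mapply(function(r, set) r %in% set, word, def$positions)))
    if (length(mism) == 0L) {
      out[[length(out) + 1L]] <- list(start = s, sub = NULL)
    } else if (allow_substitutions && length(mism) == 1L) {
      p <- mism
      alt <- def$tolerated_substitutions[[as.character(p)]]
      if (!is.null(alt) && word[p] %in% alt) {
        expected <- paste(def$positions[[p]], collapse = "/")
        out[[length(out) + 1L]] <-
          list(start = s, sub = list(position = p, expected = expected,
                                     found = word[p]))
      }
    }
  }
  out
}

#' Scan a protein for the conserved motif blocks
#'
#' Finds all raw occurrences of each block, then selects the
#' maximum-cardinality set of non-overlapping hits whose block indices
#' increase left to right along the sequence (dynamic-programming
#' chaining). Ties in cardinality are broken toward the lexicographically
#' smallest block-index tuple, then the smallest start tuple. With
#' `allow_substitutions`, matches that use a tolerated substitution (by
#' default only the block-2 terminal Y -> F) are admitted and flagged.
#'
#' @param seq non-empty protein string.
#' @param defs block definitions from [pap_block_defs()].
#' @param allow_substitutions admit tolerated substitutions. Default TRUE.
#' @return a tibble of block hits: `block_index`, `start`, `end`,
#'   `matched_word`, `ligands_present` (residues at flagged positions,
#'   collapsed with `,`), `sub_position`, `sub_expected`, `sub_found`
#'   (NA when no substitution was used).
#' @export
scan_blocks <- function(seq, defs = pap_block_defs(), allow_substitutions = TRUE) {
  seq <- check_protein(seq, "sequence")
  stopifnot(inherits(defs, "pap_blocks"))
  sc <- chars(seq)

  raw <- list()
  for (def in defs) {
    for (mt in raw_block_matches(sc, def, allow_substitutions)) {
      raw[[length(raw) + 1L]] <- list(
        block_index = def$block_index,
        start = mt$start,
        end = mt$start + length(def$positions) - 1L,
        def = def,
        sub = mt$sub
      )
    }
  }
  chained <- chain_block_hits(raw)
  block_hit_tibble(chained, sc)
}

## DP over raw hits sorted by start: longest chain with strictly increasing
## block_index and non-overlapping spans. Tie-break: smallest block-index
## tuple, then smallest start tuple (lexicographic).
chain_block_hits <- function(raw) {
  if (length(raw) == 0L) return(list())
  ord <- order(
    vapply(raw, `[[`, integer(1), "start"),
    vapply(raw, `[[`, numeric(1), "block_index")
  )
  raw <- raw[ord]
  n <- length(raw)
  best_chain <- vector("list", n) # best chain ending at hit k (indices)
  for (k in seq_len(n)) {
    best <- list(integer(0))
    for (p in seq_len(k - 1L)) {
      if (raw[[p]]$end < raw[[k]]$start &&
          raw[[p]]$block_index < raw[[k]]$block_index) {
        cand <- best_chain[[p]]
        if (chain_better(cand, best[[1L]], raw)) best <- list(cand)
      }
    }
    best_chain[[k]] <- c(best[[1L]], k)
  }
  overall <- integer(0)
  for (k in seq_len(n)) {
    if (chain_better(best_chain[[k]], overall, raw)) overall <- best_chain[[k]]
  }
  raw[overall]
}

## TRUE if chain a beats chain b: more hits; then smaller block tuple;
## then smaller start tuple.
chain_better <- function(a, b, raw) {
  if (length(a) != length(b)) return(length(a) > length(b))
  if (length(a) == 0L) return(FALSE)
  ba <- vapply(raw[a], `[[`, integer(1), "block_index")
  bb <- vapply(raw[b], `[[`, integer(1), "block_index")
  cmp <- compare_tuples(ba, bb)
  if (cmp != 0L) return(cmp < 0L)
  sa <- vapply(raw[a], `[[`, integer(1), "start")
  sb <- vapply(raw[b], `[[`, integer(1), "start")
  compare_tuples(sa, sb) < 0L
}

compare_tuples <- function(a, b) {
  for (i in seq_len(min(length(a), length(b)))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  sign(length(a) - length(b))
}

block_hit_tibble <- function(hits, seq_chars) {
  if (length(hits) == 0L) {
    return(tibble::tibble(
      block_index = integer(), start = integer(), end = integer(),
      matched_word = character(), ligands_present = character(),
      sub_position = integer(), sub_expected = character(),
      sub_found = character()
    ))
  }
  purrr::map_dfr(hits, function(h) {
    word <- seq_chars[h$start:h$end]
    lig <- word[h$def$ligand_flags]
    tibble::tibble(
      block_index = h$block_index,
      start = h$start,
      end = h$end,
      matched_word = paste(word, collapse = ""),
      ligands_present = paste(lig, collapse = ","),
      sub_position = if (is.null(h$sub)) NA_integer_ else h$sub$position,
      sub_expected = if (is.null(h$sub)) NA_character_ else h$sub$expected,
      sub_found = if (is.null(h$sub)) NA_character_ else h$sub$found
    )
  })
}

#' Classify a candidate from its block hits and scan hit
#'
#' Verdict: `pap_complete` when all five blocks are present;
#' `pap_variant` when 3-4 blocks are present and the profile score clears
#' the threshold (family members with a degraded motif set are retained on
#' profile homology); `reject` otherwise. Domain architecture is called
#' from the profile-half coverages of the scan hit: `complete` when both
#' the N- and C-terminal halves of the profile are at least half covered,
#' `partial_N` / `partial_C` when only one is, `fragmentary` otherwise.
#'
#' @param hits tibble from [scan_blocks()].
#' @param scan one-row tibble from [score_sequence()] (or the matching row
#'   of [scan_proteome()] output) for the same protein.
#' @param score_threshold bits required to retain a 3-4 block variant.
#'   Default 10, matching [scan_proteome()].
#' @param seq_length optional protein length; when given, hits beyond it
#'   raise an error.
#' @return a one-row tibble: `blocks_present` (comma-collapsed),
#'   `n_blocks`, `n_ligands`, `architecture`, `verdict`, `substitutions`.
#' @export
classify_candidate <- function(hits, scan, score_threshold = 10,
                               seq_length = NULL) {
  if (!is.null(seq_length) && nrow(hits) > 0L &&
      any(hits$end > seq_length)) {
    stop("block hit extends beyond sequence length", call. = FALSE)
  }
  blocks <- sort(unique(hits$block_index))
  n_blocks <- length(blocks)
  n_ligands <- if (nrow(hits) == 0L) 0L else {
    sum(lengths(strsplit(hits$ligands_present[hits$ligands_present != ""], ",")))
  }
  verdict <- if (n_blocks == 5L) {
    "pap_complete"
  } else if (n_blocks >= 3L && scan$score_bits >= score_threshold) {
    "pap_variant"
  } else {
    "reject"
  }
  n_ok <- scan$n_half_coverage >= 0.5
  c_ok <- scan$c_half_coverage >= 0.5
  architecture <- if (n_ok && c_ok) {
    "complete"
  } else if (n_ok) {
    "partial_N"
  } else if (c_ok) {
    "partial_C"
  } else {
    "fragmentary"
  }
  subs <- hits[!is.na(hits$sub_position), , drop = FALSE]
  sub_str <- if (nrow(subs) == 0L) "" else {
    paste(sprintf("block%d:%s%d%s", subs$block_index, subs$sub_expected,
                  subs$sub_position, subs$sub_found), collapse = ";")
  }
  tibble::tibble(
    blocks_present = paste(blocks, collapse = ","),
    n_blocks = n_blocks,
    n_ligands = as.integer(n_ligands),
    architecture = architecture,
    verdict = verdict,
    substitutions = sub_str
  )
}

#' Screen a set of scan hits against the motif blocks
#'
#' Convenience wrapper: for each protein in `hits`, runs [scan_blocks()]
#' and [classify_candidate()] and binds the per-protein records.
#'
#' @param proteome named character vector of protein sequences.
#' @param hits tibble from [scan_proteome()].
#' @param defs block definitions.
#' @param allow_substitutions passed to [scan_blocks()].
#' @param score_threshold passed to [classify_candidate()].
#' @return a tibble with one row per protein in `hits`:
#'   `protein_id`, `score_bits`, plus the [classify_candidate()] columns.
#' @export
screen_candidates <- function(proteome, hits, defs = pap_block_defs(),
                              allow_substitutions = TRUE,
                              score_threshold = 10) {
  purrr::map_dfr(seq_len(nrow(hits)), function(k) {
    id <- hits$protein_id[k]
    sq <- proteome[[id]]
    if (is.null(sq)) stop("protein '", id, "' absent from proteome", call. = FALSE)
    bh <- scan_blocks(sq, defs, allow_substitutions)
    cls <- classify_candidate(bh, hits[k, , drop = FALSE],
                              score_threshold = score_threshold,
                              seq_length = nchar(sq))
    dplyr::bind_cols(
      tibble::tibble(protein_id = id, score_bits = hits$score_bits[k]),
      cls
    )
  })
}

#' Family-level summary of screening results
#'
#' @param results tibble from [screen_candidates()] (one row per protein).
#' @return the per-protein tibble, with family tallies attached as the
#'   `tally` attribute: `all_five` (count with all 5 blocks), one row per
#'   missing-block pattern, and a substitution inventory.
#' @export
screen_report <- function(results) {
  cols <- c("protein_id", "blocks_present", "n_blocks", "n_ligands",
            "architecture", "verdict", "substitutions")
  if (nrow(results) == 0L) {
    out <- tibble::tibble(
      protein_id = character(), blocks_present = character(),
      n_blocks = integer(), n_ligands = integer(),
      architecture = character(), verdict = character(),
      substitutions = character()
    )
    attr(out, "tally") <- tibble::tibble(stat = "all_five", value = 0L)
    return(out)
  }
  dup <- results$protein_id[duplicated(results$protein_id)]
  if (length(dup) > 0L) {
    stop("duplicate protein_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::select(results, dplyr::all_of(intersect(cols, names(results))))
  missing_pattern <- vapply(results$blocks_present, function(b) {
    present <- as.integer(strsplit(b, ",")[[1]])
    miss <- setdiff(1:5, present)
    if (length(miss) == 0L) "none" else paste(miss, collapse = ",")
  }, character(1))
  tly <- dplyr::bind_rows(
    tibble::tibble(stat = "all_five",
                   value = as.integer(sum(results$n_blocks == 5L))),
    dplyr::count(
      tibble::tibble(stat = paste0("missing_", missing_pattern)),
      .data$stat, name = "value"
    ),
    tibble::tibble(
      stat = "with_substitution",
      value = as.integer(sum(results$substitutions != ""))
    )
  )
  attr(out, "tally") <- tly
  out
}
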