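#' Build a family profile from a seed multiple alignment
#'
#' Constructs a position-specific probabilistic model (a simplified Plan7
#' profile: match/insert/delete states per column, local entry and exit)
#' from an aligned set of family members. Columns whose gap fraction is at
#' most `match_gap_threshold` become match states; emissions are relative
#' residue frequencies with an additive pseudocount, and transition
#' probabilities are estimated from the observed state paths of the seed
#' sequences, also pseudocounted.
#'
#' The background model is the fixed uniform distribution over the 20
#' canonical residues, which keeps toy scores hand-checkable.
#'
#' @param msa a seed alignment: either a named character vector of aligned
#'   rows, or a list with elements `names` and `rows`. Rows must have equal
#'   length over the 20 canonical residues plus `-`.
#' @param pseudocount additive (Laplace) pseudocount for emissions and
#'   transitions. Default 1.
#' @param match_gap_threshold columns with gap fraction less than or equal
#'   to this value become match states. Default 0.5.
#' @return an object of class `pap_profile` with elements
#'   `match_emissions` (n_match x 20 probability matrix),
#'   `insert_emissions` (background 20-vector), `transitions`
#'   ((n_match - 1) x 7 probability matrix with columns MM, MI, MD, IM, II,
#'   DM, DD), `n_match`, `background`, and the build parameters.
#' @examples
#' prof <- build_profile(c(a = "DAGDE", b = "DAGDE", c = "DAGDE"))
#' prof$n_match
#' @export
build_profile <- function(msa, pseudocount = 1, match_gap_threshold = 0.5) {
  msa <- check_alignment(msa)
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be a positive real", call. = FALSE)
  }
  if (!is.numeric(match_gap_threshold) ||
      match_gap_threshold <= 0 || match_gap_threshold >= 1) {
    stop("match_gap_threshold must lie in (0, 1)", call. = FALSE)
  }
  rows <- msa$rows
  n_seq <- length(rows)
  m <- do.call(rbind, lapply(rows, chars))
  n_col <- ncol(m)

  gap_frac <- colMeans(m == GAP)
  is_match <- gap_frac <= match_gap_threshold
  match_cols <- which(is_match)
  L <- length(match_cols)
  if (L == 0L) stop("no match states", call. = FALSE)

  lambda <- pseudocount
  bg <- rep(1 / 20, 20)
  names(bg) <- AA

  ## Emissions: residue counts per match column, Laplace-smoothed.
  em <- matrix(0, nrow = L, ncol = 20, dimnames = list(NULL, AA))
  for (k in seq_len(L)) {
    col <- m[, match_cols[k]]
    col <- col[col != GAP]
    cnt <- table(factor(col, levels = AA))
    em[k, ] <- (as.numeric(cnt) + lambda) / (length(col) + 20 * lambda)
  }

  ## Transitions: walk each seed sequence's state path across consecutive
  ## match columns; residues in intervening insert columns become I states.
  ## Plan7 has no I<->D transitions; the rare I-before-delete case is
  ## counted as I->M for estimation.
  trans_names <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  transitions <- NULL
  if (L >= 2L) {
    cnt <- matrix(0, nrow = L - 1L, ncol = 7L, dimnames = list(NULL, trans_names))
    for (s in seq_len(n_seq)) {
      states <- ifelse(m[s, match_cols] == GAP, "D", "M")
      for (j in seq_len(L - 1L)) {
        lo <- match_cols[j] + 1L
        hi <- match_cols[j + 1L] - 1L
        n_ins <- if (hi >= lo) sum(m[s, lo:hi] != GAP) else 0L
        from <- states[j]
        to <- states[j + 1L]
        if (n_ins == 0L) {
          cnt[j, paste0(from, to)] <- cnt[j, paste0(from, to)] + 1
        } else {
          ## D->I and I->D are folded into the M-side counts (Plan7 bans them)
          cnt[j, "MI"] <- cnt[j, "MI"] + 1
          cnt[j, "II"] <- cnt[j, "II"] + (n_ins - 1L)
          cnt[j, "IM"] <- cnt[j, "IM"] + 1
        }
      }
    }
    transitions <- matrix(0, nrow = L - 1L, ncol = 7L,
                          dimnames = list(NULL, trans_names))
    for (j in seq_len(L - 1L)) {
      m_out <- cnt[j, c("MM", "MI", "MD")] + lambda
      i_out <- cnt[j, c("IM", "II")] + lambda
      d_out <- cnt[j, c("DM", "DD")] + lambda
      transitions[j, c("MM", "MI", "MD")] <- m_out / sum(m_out)
      transitions[j, c("IM", "II")] <- i_out / sum(i_out)
      transitions[j, c("DM", "DD")] <- d_out / sum(d_out)
    }
  }

  structure(
    list(
      match_emissions = em,
      insert_emissions = bg,
      transitions = transitions,
      n_match = L,
      background = bg,
      match_columns = match_cols,
      pseudocount = lambda,
      match_gap_threshold = match_gap_threshold,
      n_seed = n_seq
    ),
    class = "pap_profile"
  )
}

#' @export
print.pap_profile <- function(x, ...) {
  cat("<pap_profile> ", x$n_match, " match columns, built from ",
      x$n_seed, " seed sequences (pseudocount ", x$pseudocount, ")\n", sep = "")
  invisible(x)
}

## Per-column gap scores in bits, each transition charged relative to the
## same source column's M->M probability so that the straight-through
## all-match path is free and the toy score equals the bare emission sum.
profile_gap_scores <- function(profile) {
  L <- profile$n_match
  if (L < 2L) {
    z <- numeric(0)
    return(list(go_i = z, ext_i = z, close_i = z,
                open_d = z, ext_d = z, close_d = z))
  }
  tr <- profile$transitions
  mm <- tr[, "MM"]
  list(
    go_i = log2(tr[, "MI"] / mm),
    ext_i = log2(tr[, "II"] / mm),
    close_i = log2(tr[, "IM"] / mm),
    open_d = log2(tr[, "MD"] / mm),
    ext_d = log2(tr[, "DD"] / mm),
    close_d = log2(tr[, "DM"] / mm)
  )
}

#' Score a protein sequence against a family profile
#'
#' Computes the best-path (Viterbi) local log-odds score in bits against
#' the uniform background, together with the aligned span on the protein,
#' the fraction of match columns used, and the coverage of the profile's
#' N-terminal and C-terminal halves (split at `ceiling(n_match / 2)`).
#' A forward score (log-odds of the sum over all local paths) is returned
#' alongside and is always at least the Viterbi score.
#'
#' Local entry and exit are uniform over the match columns and are charged
#' to the score: every path pays `2 * log2(1/n_match)` bits (once for
#' entry, once for exit), which keeps the score of random sequences near
#' or below zero instead of growing with the search space. Gap transitions
#' are charged in bits relative to each column's match-to-match
#' probability, so an ungapped full-length match scores the sum of
#' per-column emission log-odds plus the constant entry/exit charge.
#'
#' @param profile a `pap_profile`.
#' @param seq a non-empty protein string over the canonical alphabet.
#' @return a one-row tibble: `score_bits`, `forward_bits`, `start`, `end`
#'   (1-based inclusive on the protein), `match_coverage`,
#'   `n_half_coverage`, `c_half_coverage`, `n_match_used`.
#' @export
score_sequence <- function(profile, seq) {
  stopifnot(inherits(profile, "pap_profile"))
  seq <- check_protein(seq, "query")
  s <- chars(seq)
  n <- length(s)
  L <- profile$n_match
  em_lo <- log2(profile$match_emissions / (1 / 20)) # L x 20
  gs <- profile_gap_scores(profile)
  NEG <- -Inf

  VM <- matrix(NEG, nrow = L, ncol = n)
  VI <- matrix(NEG, nrow = L, ncol = n) # I_j: insert after column j
  VD <- matrix(NEG, nrow = L, ncol = n)

  res_idx <- match(s, AA)
  for (j in seq_len(L)) {
    e <- em_lo[j, res_idx]
    if (j == 1L) {
      VM[1L, ] <- e # free local entry
    } else {
      prev <- c(NEG, pmax(
        VM[j - 1L, -n],
        VI[j - 1L, -n] + gs$close_i[j - 1L],
        VD[j - 1L, -n] + gs$close_d[j - 1L]
      ))
      VM[j, ] <- e + pmax(prev, 0) # 0 = fresh local entry at column j
      VD[j, ] <- pmax(VM[j - 1L, ] + gs$open_d[j - 1L],
                      VD[j - 1L, ] + gs$ext_d[j - 1L])
    }
    if (j < L && n >= 2L) {
      ## max-plus prefix scan: VI[j,i] = go + c*(i-1) + cummax(VM[j,k] - c*k)
      cc <- gs$ext_i[j]
      k <- seq_len(n - 1L)
      run <- cummax(VM[j, k] - cc * k)
      VI[j, 2:n] <- gs$go_i[j] + cc * (k + 1L - 1L) + run
    }
  }

  best <- which(VM == max(VM), arr.ind = TRUE)
  ## deterministic tie-break: smallest end residue, then smallest column
  best <- best[order(best[, 2L], best[, 1L]), , drop = FALSE]
  j_end <- unname(best[1L, 1L])
  i_end <- unname(best[1L, 2L])
  vit <- VM[j_end, i_end]

  ## Traceback to recover the span and the set of matched columns. The
  ## DP is vectorized so predecessors are re-identified cell by cell; any
  ## predecessor reproducing the cell value lies on an optimal path.
  tol <- 1e-7
  used_m <- logical(L)
  j <- j_end; i <- i_end; state <- "M"
  i_start <- i_end
  repeat {
    if (state == "M") {
      used_m[j] <- TRUE
      i_start <- i
      if (j == 1L || i == 1L) break # only fresh entry can precede
      target <- VM[j, i] - em_lo[j, res_idx[i]]
      cands <- c(
        M = VM[j - 1L, i - 1L],
        D = VD[j - 1L, i - 1L] + gs$close_d[j - 1L],
        I = VI[j - 1L, i - 1L] + gs$close_i[j - 1L],
        entry = 0
      )
      pick <- names(cands)[which(abs(cands - target) < tol)][1L]
      if (is.na(pick) || pick == "entry") break
      j <- j - 1L; i <- i - 1L; state <- pick
    } else if (state == "I") { # I_j after column j, residues up to i
      if (i > 1L &&
          abs(VI[j, i] - (VI[j, i - 1L] + gs$ext_i[j])) < tol) {
        i <- i - 1L
      } else {
        state <- "M"
        i <- i - 1L
      }
    } else { # D at column j, residues up to i
      if (j > 2L &&
          abs(VD[j, i] - (VD[j - 1L, i] + gs$ext_d[j - 1L])) < tol) {
        j <- j - 1L
      } else {
        state <- "M"
        j <- j - 1L
      }
    }
  }

  half <- ceiling(L / 2)
  n_used <- sum(used_m)
  entry_exit <- 2 * log2(1 / L) # uniform local entry + exit, paid once
  fwd <- forward_bits(profile, seq) + entry_exit

  tibble::tibble(
    score_bits = vit + entry_exit,
    forward_bits = fwd,
    start = as.integer(unname(i_start)),
    end = as.integer(unname(i_end)),
    match_coverage = n_used / L,
    n_half_coverage = sum(used_m[seq_len(half)]) / half,
    c_half_coverage = if (L > half) sum(used_m[(half + 1L):L]) / (L - half) else 0,
    n_match_used = n_used
  )
}

## Forward (sum over all local paths) log-odds score in bits.
forward_bits <- function(profile, seq) {
  seq <- check_protein(seq, "query")
  s <- chars(seq)
  n <- length(s)
  L <- profile$n_match
  em_lo <- log2(profile$match_emissions / (1 / 20))
  gs <- profile_gap_scores(profile)

  FM <- matrix(-Inf, nrow = L, ncol = n)
  FI <- matrix(-Inf, nrow = L, ncol = n)
  FD <- matrix(-Inf, nrow = L, ncol = n)
  res_idx <- match(s, AA)

  l2se2 <- function(a, b) {
    m <- pmax(a, b)
    out <- m + log2(2^(a - m) + 2^(b - m))
    out[!is.finite(m)] <- -Inf
    out
  }
  for (j in seq_len(L)) {
    e <- em_lo[j, res_idx]
    if (j == 1L) {
      FM[1L, ] <- e
    } else {
      prev <- c(-Inf, l2se2(
        l2se2(FM[j - 1L, -n], FI[j - 1L, -n] + gs$close_i[j - 1L]),
        FD[j - 1L, -n] + gs$close_d[j - 1L]
      ))
      FM[j, ] <- e + l2se2(prev, rep(0, n)) # + fresh entry
      FD[j, ] <- l2se2(FM[j - 1L, ] + gs$open_d[j - 1L],
                       FD[j - 1L, ] + gs$ext_d[j - 1L])
    }
    if (j < L && n >= 2L) {
      cc <- gs$ext_i[j]
      k <- seq_len(n - 1L)
      off <- max(FM[j, k] - cc * k)
      if (is.finite(off)) {
        run <- log2(cumsum(2^(FM[j, k] - cc * k - off))) + off
        FI[j, 2:n] <- gs$go_i[j] + cc * k + run
      }
    }
  }
  log2sumexp(as.vector(FM)) # free exit from any match cell
}

#' Scan a proteome for candidate family members
#'
#' Scores every protein against the profile and returns hits at or above
#' the score threshold, sorted by descending score (ties broken by
#' protein id). The default threshold of 10 bits is deliberately
#' permissive: candidates are expected to be verified downstream by the
#' conserved-motif screen.
#'
#' @param profile a `pap_profile`.
#' @param proteome a named character vector of protein sequences, or the
#'   path to a protein FASTA file.
#' @param score_threshold minimum Viterbi score in bits. Default 10.
#' @return a tibble of hits: `protein_id`, `score_bits`, `forward_bits`,
#'   `start`, `end`, `match_coverage`, `n_half_coverage`,
#'   `c_half_coverage`.
#' @export
scan_proteome <- function(profile, proteome, score_threshold = 10) {
  stopifnot(inherits(profile, "pap_profile"))
  if (!is.numeric(score_threshold) || length(score_threshold) != 1L ||
      is.na(score_threshold) || score_threshold == Inf) {
    if (!identical(score_threshold, -Inf)) {
      stop("score_threshold must be a finite number or -Inf", call. = FALSE)
    }
  }
  if (is.character(proteome) && length(proteome) == 1L &&
      is.null(names(proteome)) && file.exists(proteome)) {
    proteome <- read_protein_fasta(proteome)
  }
  if (length(proteome) == 0L) {
    return(tibble::tibble(
      protein_id = character(), score_bits = numeric(),
      forward_bits = numeric(), start = integer(), end = integer(),
      match_coverage = numeric(), n_half_coverage = numeric(),
      c_half_coverage = numeric(), n_match_used = integer()
    ))
  }
  if (is.null(names(proteome)) || anyNA(names(proteome)) ||
      any(names(proteome) == "")) {
    stop("proteome sequences must be named", call. = FALSE)
  }
  hits <- purrr::imap(proteome, function(sq, id) {
    row <- tryCatch(
      score_sequence(profile, sq),
      error = function(e) stop("record '", id, "': ", conditionMessage(e),
                               call. = FALSE)
    )
    dplyr::mutate(row, protein_id = id, .before = 1L)
  })
  out <- dplyr::bind_rows(hits)
  out <- dplyr::filter(out, .data$score_bits >= score_threshold)
  dplyr::arrange(out, dplyr::desc(.data$score_bits), .data$protein_id)
}

#' Serialize a family profile to a versioned JSON document
#' @param profile a `pap_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_json <- function(profile, path) {
  stopifnot(inherits(profile, "pap_profile"))
  doc <- list(
    format = "papfam-profile",
    format_version = 1L,
    n_match = profile$n_match,
    alphabet = AA,
    background = unname(profile$background),
    match_emissions = unname(apply(profile$match_emissions, 1L, c, simplify = FALSE)),
    transitions = if (is.null(profile$transitions)) NULL else {
      list(names = colnames(profile$transitions),
           rows = unname(apply(profile$transitions, 1L, c, simplify = FALSE)))
    },
    match_columns = profile$match_columns,
    pseudocount = profile$pseudocount,
    match_gap_threshold = profile$match_gap_threshold,
    n_seed = profile$n_seed
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a family profile from its JSON serialization
#' @param path path written by [write_profile_json()].
#' @return a `pap_profile`.
#' @export
read_profile_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "papfam-profile")) {
    stop("not a papfam profile document", call. = FALSE)
  }
  as_mat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
  em <- as_mat(doc$match_emissions)
  colnames(em) <- AA
  tr <- NULL
  if (!is.null(doc$transitions) && length(doc$transitions) > 0L) {
    tr <- as_mat(doc$transitions$rows)
    colnames(tr) <- doc$transitions$names
  }
  bg <- doc$background
  names(bg) <- AA
  structure(
    list(
      match_emissions = em,
      insert_emissions = bg,
      transitions = tr,
      n_match = doc$n_match,
      background = bg,
      match_columns = doc$match_columns,
      pseudocount = doc$pseudocount,
      match_gap_threshold = doc$match_gap_threshold,
      n_seed = doc$n_seed
    ),
    class = "pap_profile"
  )
}
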