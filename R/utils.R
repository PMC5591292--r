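#' @keywords internal
#' @importFrom rlang .data %||%
#' @importFrom ggplot2 autoplot
#' @importFrom generics tidy glance
"_PACKAGE"

## Canonical alphabets used throughout. Gap symbol is '-' only; '*' (stop)
## is stripped on FASTA import with a warning.
AA <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
GAP <- "-"
DNA <- c("A", "C", "G", "T")

## IUPAC nucleotide degeneracy codes -> the plain bases each matches.
## An ambiguous base in the *subject* never matches anything.
IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Split a protein or nucleotide string into single characters
#' @noRd
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Validate a protein sequence over the 20-letter alphabet
#' @noRd
check_protein <- function(seq, what = "sequence") {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq) || nchar(seq) == 0L) {
    stop(what, " must be a non-empty protein string", call. = FALSE)
  }
  cs <- chars(toupper(seq))
  bad <- which(!cs %in% AA)
  if (length(bad) > 0L) {
    stop(
      what, " contains non-canonical residue '", cs[bad[1L]],
      "' at position ", bad[1L],
      call. = FALSE
    )
  }
  paste(cs, collapse = "")
}

#' Validate a nucleotide string over {A,C,G,T,N}
#' @noRd
check_dna <- function(seq, what = "sequence", allow_n = TRUE) {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq) || nchar(seq) == 0L) {
    stop(what, " must be a non-empty nucleotide string", call. = FALSE)
  }
  cs <- chars(toupper(seq))
  ok <- if (allow_n) c(DNA, "N") else DNA
  bad <- which(!cs %in% ok)
  if (length(bad) > 0L) {
    stop(
      what, " contains unsupported base '", cs[bad[1L]],
      "' at position ", bad[1L],
      call. = FALSE
    )
  }
  paste(cs, collapse = "")
}

#' Reverse complement of a plain {A,C,G,T,N} string
#' @noRd
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[chars(toupper(x))])), collapse = "")
}

#' Deterministic child seeds for the synthetic-data generators
#'
#' Every generator draws its randomness from a child seed derived from the
#' user's single seed and a fixed per-generator stream index, so adding a
#' generator (or calling them in a different order) never perturbs the
#' output of another. The rule is a fixed affine map modulo a Mersenne
#' prime, kept below 2^31 so the result is always a valid R integer seed.
#'
#' @param seed single integer master seed.
#' @param stream fixed per-generator stream index (small integer).
#' @return an integer seed.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1
  as.integer((abs(seed) %% m * 48271 + 7919 * stream) %% m)
}

#' Evaluate an expression under a local RNG seed
#' @noRd
with_seed <- function(seed, expr) {
  seed <- as.integer(seed) # force now: the caller may draw it from the RNG
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Read a protein FASTA file into a named character vector
#'
#' Wrapped or single-line FASTA is accepted. Trailing stop symbols `*` are
#' stripped with a warning naming the records affected.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("cannot read FASTA '", path, "': ", conditionMessage(e), call. = FALSE)
  )
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  has_stop <- grepl("*", seqs, fixed = TRUE)
  if (any(has_stop)) {
    warning(
      "stripped '*' stop symbols from: ",
      paste(names(seqs)[has_stop], collapse = ", "),
      call. = FALSE
    )
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  seqs
}

#' Read a nucleotide FASTA file into a named character vector
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_dna_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("cannot read FASTA '", path, "': ", conditionMessage(e), call. = FALSE)
  )
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write a named character vector of sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param type "AA" or "DNA".
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs) else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Validate a seed alignment (names + equal-length aligned rows)
#' @noRd
check_alignment <- function(msa) {
  if (is.character(msa)) {
    msa <- list(names = names(msa) %||% paste0("seq", seq_along(msa)), rows = unname(msa))
  }
  stopifnot(is.list(msa), !is.null(msa$rows))
  rows <- toupper(msa$rows)
  if (length(rows) < 2L) stop("alignment needs >= 2 rows", call. = FALSE)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) stop("alignment rows differ in length", call. = FALSE)
  ok <- c(AA, GAP)
  for (i in seq_along(rows)) {
    cs <- chars(rows[i])
    bad <- which(!cs %in% ok)
    if (length(bad) > 0L) {
      stop(
        "alignment row ", i, " has invalid symbol '", cs[bad[1L]],
        "' at column ", bad[1L],
        call. = FALSE
      )
    }
  }
  list(names = msa$names %||% paste0("seq", seq_along(rows)), rows = rows)
}

log2sumexp <- function(x) {
  x <- x[is.finite(x) | x > -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log2(sum(2^(x - m)))
}
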