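## Average (not monoisotopic) residue masses in daltons, ExPASy convention.
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01528

## Bjellqvist pKa set (the set behind the ExPASy Compute pI tool).
## Side chains, C-terminus, and residue-specific N-terminal pKa values.
PKA_SIDE <- c(C = 9.0, D = 4.05, E = 4.45, H = 5.98, K = 10.0, R = 12.0, Y = 10.0)
PKA_CTERM <- 3.55
PKA_NTERM <- c(
  A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44, E = 7.7,
  G = 7.5, default = 7.5
)

#' Molecular weight of a protein (average isotopic masses)
#'
#' Sum of average residue masses plus one water.
#'
#' @param seq non-empty protein string over the canonical alphabet.
#' @return mass in daltons.
#' @examples
#' molecular_weight("G") # 75.07 Da
#' @export
molecular_weight <- function(seq) {
  seq <- check_protein(seq, "sequence")
  sum(AA_AVG_MASS[chars(seq)]) + WATER_MASS
}

#' Net charge of a protein at a given pH (Henderson-Hasselbalch)
#'
#' Termini plus D, E, C, Y, H, K, R side chains under the Bjellqvist pKa
#' set. The N-terminal pKa is residue-specific, following the ExPASy
#' convention.
#'
#' @param seq protein string.
#' @param ph pH value (vectorized).
#' @return net charge at each pH.
#' @export
net_charge <- function(seq, ph) {
  seq <- check_protein(seq, "sequence")
  cs <- chars(seq)
  n_term_pka <- PKA_NTERM[cs[1L]]
  if (is.na(n_term_pka)) n_term_pka <- PKA_NTERM[["default"]]
  pos_pka <- c(n_term_pka,
               rep(PKA_SIDE[["H"]], sum(cs == "H")),
               rep(PKA_SIDE[["K"]], sum(cs == "K")),
               rep(PKA_SIDE[["R"]], sum(cs == "R")))
  neg_pka <- c(PKA_CTERM,
               rep(PKA_SIDE[["D"]], sum(cs == "D")),
               rep(PKA_SIDE[["E"]], sum(cs == "E")),
               rep(PKA_SIDE[["C"]], sum(cs == "C")),
               rep(PKA_SIDE[["Y"]], sum(cs == "Y")))
  vapply(ph, function(p) {
    sum(1 / (1 + 10^(p - pos_pka))) - sum(1 / (1 + 10^(neg_pka - p)))
  }, numeric(1))
}

#' Isoelectric point of a protein
#'
#' The pH at which the net charge is zero, found by bisection on
#' [net_charge()] to |charge| < 1e-4. The charge function is strictly
#' decreasing in pH, so the root is unique.
#'
#' @param seq non-empty protein string.
#' @return pI in pH units (bounded to (0, 14)).
#' @export
isoelectric_point <- function(seq) {
  seq <- check_protein(seq, "sequence")
  lo <- 0
  hi <- 14
  for (k in seq_len(200)) {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid)
    if (abs(q) < 1e-4) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' N-glycosylation sequons (N-X(not P)-[S/T])
#'
#' A simple sequon scan: positions `i` with `seq[i] == N`,
#' `seq[i+1] != P` and `seq[i+2]` in S/T. This is an explicitly simplified
#' stand-in for trained glycosylation-site predictors; externally produced
#' predictor calls can be carried as an annotation column instead.
#'
#' @param seq non-empty protein string.
#' @return integer vector of 1-based sequon start positions (possibly
#'   overlapping).
#' @examples
#' glyco_sequons("NGS") # 1
#' glyco_sequons("NPS") # integer(0)
#' @export
glyco_sequons <- function(seq) {
  seq <- check_protein(seq, "sequence")
  cs <- chars(seq)
  n <- length(cs)
  if (n < 3L) return(integer(0))
  i <- seq_len(n - 2L)
  i[cs[i] == "N" & cs[i + 1L] != "P" & cs[i + 2L] %in% c("S", "T")]
}

#' Default promoter cis-element definitions
#'
#' P1BS (PHR1-binding site, GNATATNC), the W-box (TTGACY), the TC element
#' (TCTCTCT) and the NIT2-like element (AAATATCT), the phosphate- and
#' stress-responsive boxes relevant to PAP promoters.
#'
#' @return tibble: `name`, `pattern`, `scan_both_strands`.
#' @export
cis_element_defs <- function() {
  tibble::tibble(
    name = c("P1BS", "Wbox", "TC", "NIT2"),
    pattern = c("GNATATNC", "TTGACY", "TCTCTCT", "AAATATCT"),
    scan_both_strands = TRUE
  )
}

## IUPAC degenerate pattern -> regex character classes over plain ACGT
## (an ambiguous base in the promoter never matches anything).
iupac_to_regex <- function(pattern) {
  cs <- chars(toupper(pattern))
  bad <- setdiff(cs, names(IUPAC_DNA))
  if (length(bad) > 0L) {
    stop("unsupported degeneracy code '", bad[1], "' in pattern '",
         pattern, "'", call. = FALSE)
  }
  paste(vapply(cs, function(b) {
    set <- IUPAC_DNA[[b]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

## IUPAC reverse complement (degeneracy-aware).
iupac_revcomp <- function(pattern) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(unname(comp[chars(toupper(pattern))])), collapse = "")
}

## All (overlapping) match starts of a regex in a string.
regex_starts <- function(string, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), string, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Scan a promoter for degenerate cis-elements
#'
#' Reports every window of the promoter matching each element's IUPAC
#' degenerate pattern. When an element is scanned on both strands, windows
#' whose reverse complement matches are reported on strand `-` with the
#' plus-strand start coordinate. Ambiguous bases (`N`) in the promoter
#' never match. Hits are sorted by start, then element name, then strand.
#'
#' @param promoter nucleotide string over A/C/G/T/N, conventionally the
#'   3 kb upstream region, 1-based from its 5' end.
#' @param defs tibble of element definitions (see [cis_element_defs()]).
#' @param promoter_id optional id carried into the output.
#' @return tibble of `CisElementHit`: `promoter_id`, `element`, `start`,
#'   `strand`, `matched_word` (the plus-strand word at the window).
#' @examples
#' scan_promoter("GAATATCC", cis_element_defs()[1, ])
#' @export
scan_promoter <- function(promoter, defs = cis_element_defs(),
                          promoter_id = NA_character_) {
  promoter <- check_dna(promoter, "promoter")
  out <- purrr::map_dfr(seq_len(nrow(defs)), function(k) {
    pat <- defs$pattern[k]
    w <- nchar(pat)
    fwd <- regex_starts(promoter, iupac_to_regex(pat))
    rows <- tibble::tibble(
      promoter_id = promoter_id, element = defs$name[k],
      start = fwd, strand = "+"
    )
    ## a self-reverse-complementary pattern (e.g. P1BS) matches both
    ## strands at every site; report such windows once, on '+'
    if (isTRUE(defs$scan_both_strands[k]) && iupac_revcomp(pat) != toupper(pat)) {
      rev_starts <- regex_starts(promoter, iupac_to_regex(iupac_revcomp(pat)))
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        promoter_id = promoter_id, element = defs$name[k],
        start = rev_starts, strand = "-"
      ))
    }
    rows$matched_word <- substr(rep(promoter, nrow(rows)), rows$start,
                                rows$start + w - 1L)
    rows
  })
  dplyr::arrange(out, .data$start, .data$element, .data$strand)
}

#' Export cis-element hits as BED (0-based half-open)
#'
#' @param hits tibble from [scan_promoter()], with an extra `width` column
#'   optional; widths are recovered from `matched_word`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cis_bed <- function(hits, path) {
  bed <- data.frame(
    chrom = hits$promoter_id,
    start = hits$start - 1L,
    end = hits$start - 1L + nchar(hits$matched_word),
    name = hits$element,
    score = 0L,
    strand = hits$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Infer exon/intron structure by spliced embedding of the CDS
#'
#' Chains the CDS into the genomic sequence as a series of exact exon
#' segments separated by introns, by greedy longest-exact-extension with
#' earliest placement: exact when exon segments are unique in the genomic
#' sequence and at least ~10 bp, the regime in which gene structures are
#' recoverable from a cDNA-genomic comparison at all. With
#' `strict_splice_sites`, every intron must begin with GT and end with AG.
#'
#' @param cds non-empty coding sequence (A/C/G/T).
#' @param genomic genomic sequence containing the spliced CDS.
#' @param strict_splice_sites require canonical GT..AG introns. Default
#'   FALSE.
#' @param gene_id optional id carried into the output.
#' @return a list of class `GeneStructure`: `gene_id`, `exon_count`,
#'   `exons` (tibble with `start`, `end`, 1-based inclusive on the
#'   genomic sequence).
#' @export
infer_gene_structure <- function(cds, genomic, strict_splice_sites = FALSE,
                                 gene_id = NA_character_) {
  cds <- check_dna(cds, "cds", allow_n = FALSE)
  genomic <- check_dna(genomic, "genomic", allow_n = FALSE)
  n <- nchar(cds)
  g <- nchar(genomic)
  cds_c <- chars(cds)
  gen_c <- chars(genomic)

  spans <- list()
  c_pos <- 1L # next CDS base to place
  g_min <- 1L # earliest admissible genomic start
  while (c_pos <= n) {
    ## candidate starts: genomic occurrences of the next CDS base
    cand <- which(gen_c == cds_c[c_pos])
    cand <- cand[cand >= g_min]
    if (length(cand) == 0L) stop("CDS not embeddable", call. = FALSE)
    ## longest exact extension at each candidate start
    best_len <- 0L
    best_start <- NA_integer_
    for (st in cand) {
      len <- 0L
      while (c_pos + len <= n && st + len <= g &&
             cds_c[c_pos + len] == gen_c[st + len]) {
        len <- len + 1L
      }
      if (strict_splice_sites && c_pos + len <= n) {
        ## segment must be followed by a GT intron start (unless last exon)
        while (len > 0L &&
               !(st + len + 1L <= g &&
                 gen_c[st + len] == "G" && gen_c[st + len + 1L] == "T")) {
          len <- len - 1L
        }
        if (len == 0L) next
      }
      if (len > best_len) { # earliest placement wins ties
        best_len <- len
        best_start <- st
      }
    }
    if (best_len == 0L) stop("CDS not embeddable", call. = FALSE)
    spans[[length(spans) + 1L]] <- c(best_start, best_start + best_len - 1L)
    c_pos <- c_pos + best_len
    g_min <- best_start + best_len + 1L # at least one intron base
  }
  if (strict_splice_sites && length(spans) > 1L) {
    for (k in 2L:length(spans)) {
      intron_start <- spans[[k - 1L]][2L] + 1L
      intron_end <- spans[[k]][1L] - 1L
      ok <- intron_end - intron_start + 1L >= 4L &&
        gen_c[intron_start] == "G" && gen_c[intron_start + 1L] == "T" &&
        gen_c[intron_end - 1L] == "A" && gen_c[intron_end] == "G"
      if (!ok) stop("CDS not embeddable with canonical splice sites",
                    call. = FALSE)
    }
  }
  exons <- tibble::tibble(
    start = vapply(spans, `[[`, numeric(1), 1L),
    end = vapply(spans, `[[`, numeric(1), 2L)
  )
  structure(
    list(gene_id = gene_id, exon_count = nrow(exons), exons = exons),
    class = "GeneStructure"
  )
}

#' @export
print.GeneStructure <- function(x, ...) {
  cat("<GeneStructure> ", if (!is.na(x$gene_id)) paste0(x$gene_id, ": "),
      x$exon_count, " exon(s)\n", sep = "")
  invisible(x)
}

#' Physico-chemical and sequon annotation of a protein set
#'
#' One row per protein: length, molecular weight, pI, sequon count.
#' Externally produced predictor calls (signal peptide, subcellular
#' localization, peroxisomal targeting, trained glycosylation predictions)
#' can be joined on via `external`, a tibble keyed by `protein_id`.
#'
#' @param proteins named character vector of protein sequences.
#' @param external optional tibble keyed by `protein_id` with extra
#'   annotation columns, left-joined onto the result.
#' @return tibble: `protein_id`, `length`, `mw`, `pi`, `n_sequons`, plus
#'   any external columns.
#' @export
annotate_proteins <- function(proteins, external = NULL) {
  out <- purrr::imap_dfr(proteins, function(sq, id) {
    tibble::tibble(
      protein_id = id,
      length = nchar(sq),
      mw = molecular_weight(sq),
      pi = isoelectric_point(sq),
      n_sequons = length(glyco_sequons(sq))
    )
  })
  if (!is.null(external)) {
    stopifnot("protein_id" %in% names(external))
    out <- dplyr::left_join(out, external, by = "protein_id")
  }
  out
}
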