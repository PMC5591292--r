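# Independent oracles used by the property tests. These deliberately take
# the slow, enumerative route so they share no code path with the package.

# All residues
.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# --- profile scoring oracle: enumerate every local state path ------------
# A path aligns query residues i1..i2 to a walk through match columns
# s..e with optional deletions/insertions. Scores follow the package's
# documented convention (emission log-odds; transitions charged relative
# to the source column's M->M), but the enumeration is exhaustive rather
# than DP.
oracle_viterbi <- function(profile, seq) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  L <- profile$n_match
  em_lo <- log2(profile$match_emissions / (1 / 20))
  tr <- profile$transitions
  gap <- function(kind, j) {
    if (is.null(tr)) return(-Inf)
    mm <- tr[j, "MM"]
    switch(kind,
      go_i = log2(tr[j, "MI"] / mm),
      ext_i = log2(tr[j, "II"] / mm),
      close_i = log2(tr[j, "IM"] / mm),
      open_d = log2(tr[j, "MD"] / mm),
      ext_d = log2(tr[j, "DD"] / mm),
      close_d = log2(tr[j, "DM"] / mm)
    )
  }
  best <- -Inf
  # recursive enumeration: state after consuming residue i at column j
  # states: "M" (just matched col j with residue i)
  # From M(j, i): stop; or advance to M(j+dj, i+1) paying deletions for
  # dj>1; or insert k>=1 residues then match column j+dj.
  recurse <- function(j, i, score) {
    best <<- max(best, score)
    if (i >= n || j >= L) return()
    # direct or delete-skipping advance, no inserts
    for (j2 in (j + 1):L) {
      pay <- 0
      if (j2 == j + 1) {
        pay <- 0 # M->M is free by convention
      } else {
        pay <- gap("open_d", j)
        if (j2 - j - 1 >= 2) {
          for (jd in (j + 1):(j2 - 2)) pay <- pay + gap("ext_d", jd)
        }
        pay <- pay + gap("close_d", j2 - 1)
      }
      recurse(j2, i + 1, score + pay + em_lo[j2, match(s[i + 1], .AA)])
    }
    # insertions of length k then advance one column (inserts sit between
    # columns j and j+1; the package model resumes at column j+1)
    max_k <- n - i - 1
    if (max_k >= 1 && j + 1 <= L) {
      for (k in 1:max_k) {
        pay <- gap("go_i", j) + (k - 1) * gap("ext_i", j) + gap("close_i", j)
        recurse(j + 1, i + k + 1,
                score + pay + em_lo[j + 1, match(s[i + k + 1], .AA)])
      }
    }
  }
  for (j in 1:L) {
    for (i in 1:n) {
      recurse(j, i, em_lo[j, match(s[i], .AA)])
    }
  }
  best + 2 * log2(1 / L) # uniform local entry + exit charge
}

# --- block chaining oracle: enumerate ordered hit subsets ----------------
# raw: data.frame(block_index, start, end). Returns the best chain under
# the package's stated rule: max cardinality, then smallest block-index
# tuple, then smallest start tuple.
oracle_chain <- function(raw) {
  n <- nrow(raw)
  if (n == 0) return(integer(0))
  best <- integer(0)
  better <- function(a, b) {
    if (length(a) != length(b)) return(length(a) > length(b))
    if (length(a) == 0) return(FALSE)
    ba <- raw$block_index[a]; bb <- raw$block_index[b]
    for (i in seq_along(ba)) {
      if (ba[i] != bb[i]) return(ba[i] < bb[i])
    }
    sa <- raw$start[a]; sb <- raw$start[b]
    for (i in seq_along(sa)) {
      if (sa[i] != sb[i]) return(sa[i] < sb[i])
    }
    FALSE
  }
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) < 2) {
      ok <- TRUE
    } else {
      idx <- idx[order(raw$start[idx])]
      ok <- all(diff(raw$block_index[idx]) > 0) &&
        all(raw$end[idx][-length(idx)] < raw$start[idx][-1])
    }
    if (ok && better(idx, best)) best <- idx
  }
  best
}

# --- protein charge oracle (independent closed form + uniroot) -----------
oracle_pi <- function(seq) {
  cs <- strsplit(seq, "")[[1]]
  nt <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44, E = 7.7)
  ntp <- if (cs[1] %in% names(nt)) nt[[cs[1]]] else 7.5
  counts <- table(factor(cs, levels = .AA))
  charge <- function(ph) {
    pos <- 1 / (1 + 10^(ph - ntp)) +
      counts[["H"]] / (1 + 10^(ph - 5.98)) +
      counts[["K"]] / (1 + 10^(ph - 10.0)) +
      counts[["R"]] / (1 + 10^(ph - 12.0))
    neg <- 1 / (1 + 10^(3.55 - ph)) +
      counts[["D"]] / (1 + 10^(4.05 - ph)) +
      counts[["E"]] / (1 + 10^(4.45 - ph)) +
      counts[["C"]] / (1 + 10^(9.0 - ph)) +
      counts[["Y"]] / (1 + 10^(10.0 - ph))
    pos - neg
  }
  uniroot(charge, c(0, 14), tol = 1e-9)$root
}

oracle_mw <- function(seq) {
  mass <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
            C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
            H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
            M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
            T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
  sum(mass[strsplit(seq, "")[[1]]]) + 18.01528
}

# --- random additive tree/matrix pair ------------------------------------
random_additive <- function(n_taxa) {
  tree <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(k) runif(k, 0.1, 1))
  d <- ape::cophenetic.phylo(tree)
  labs <- sort(rownames(d))
  list(tree = tree, d = d[labs, labs])
}

# --- subgroup assignment oracle: exhaustive clade check ------------------
oracle_subgroup <- function(tree, reference_labels, query) {
  rooted <- phangorn::midpoint(tree)
  n_tip <- length(rooted$tip.label)
  clades <- lapply(seq_len(rooted$Nnode) + n_tip, function(nd) {
    rooted$tip.label[phangorn::Descendants(rooted, nd, "tips")[[1]]]
  })
  refs <- names(reference_labels)
  keep <- Filter(function(cl) query %in% cl && any(cl %in% refs), clades)
  if (length(keep) == 0) return("unclassified")
  cl <- keep[[which.min(lengths(keep))]]
  sg <- unique(unname(reference_labels[intersect(cl, refs)]))
  if (length(sg) == 1) sg else "unclassified"
}

random_peptide <- function(len) {
  paste(sample(.AA, len, replace = TRUE), collapse = "")
}
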