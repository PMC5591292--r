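## Synthetic-data generators. Every generator is a pure function of its
## parameters and seed: the master seed fans out to fixed per-generator
## streams via child_seed(), so adding a generator never perturbs the
## output of another. Stream indices:
##   1 proteome, 2 promoters, 3 msa, 4 geno/pheno, 5 ct table, 6 gene models

rand_protein <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")
rand_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

## sample() that never falls into the scalar-x trap
pick1 <- function(x) x[sample.int(length(x), 1L)]

#' Default degradation specification for the synthetic PAP family
#'
#' Four deviants mirroring the degraded-motif patterns seen in real plant
#' PAP families: one member missing block 4 with the block-2 Y -> F
#' substitution, one missing block 5, one missing blocks 3 and 5 with the
#' C-terminal family signal degraded (N-domain-only architecture), and one
#' missing block 4 with the N-terminal signal degraded (C-domain-only).
#'
#' @return a list of deviant descriptors with elements `label`,
#'   `drop_blocks`, `y2f`, `degrade_half` (`"none"`, `"C"` or `"N"` — the
#'   half whose family signal is destroyed).
#' @export
default_degradation_spec <- function() {
  list(
    list(label = "missing4_y2f", drop_blocks = 4L, y2f = TRUE, degrade_half = "none"),
    list(label = "missing5", drop_blocks = 5L, y2f = FALSE, degrade_half = "none"),
    list(label = "missing3_5_Nonly", drop_blocks = c(3L, 5L), y2f = FALSE, degrade_half = "C"),
    list(label = "missing4_Conly", drop_blocks = 4L, y2f = FALSE, degrade_half = "N")
  )
}

#' Simulate a proteome containing a planted motif-block family
#'
#' Family members derive from a single random family template in which
#' the five conserved blocks are planted, in order, at random spacings;
#' each member copies the template with a fixed per-site substitution
#' probability outside the blocks (blocks stay exact), so the members form
#' an implicitly aligned family. Deviants (from `degradation_spec`) have
#' the listed blocks overwritten with random residues, optionally carry
#' the block-2 Y -> F substitution, and optionally have one half's family
#' signal randomized (emulating single-domain architectures).
#' `n_y2f_complete` additional members keep all five blocks but carry
#' Y -> F. Decoys are residue-shuffled members (composition preserved,
#' blocks destroyed).
#'
#' @param n_members family size including deviants. Default 25, the size
#'   of a typical plant PAP family.
#' @param n_decoys number of shuffled decoys. Default 50.
#' @param degradation_spec list of deviant descriptors
#'   (see [default_degradation_spec()]); deviants occupy the last member
#'   slots.
#' @param n_y2f_complete complete members carrying Y -> F. Default 2.
#' @param seed integer seed.
#' @param template_length core template length before blocks. Default 170.
#' @param sub_prob per-site substitution probability off the blocks.
#'   Default 0.1.
#' @param defs block definitions.
#' @return list: `proteome` (named character vector, members then
#'   decoys), `seed_msa` (the member sequences as an ungapped alignment),
#'   `truth` (tibble: `id`, `role`, `blocks_present`, `substitutions`,
#'   `label`), `params`.
#' @export
make_family_proteome <- function(n_members = 25, n_decoys = 50,
                                 degradation_spec = default_degradation_spec(),
                                 n_y2f_complete = 2, seed = 1,
                                 template_length = 170, sub_prob = 0.1,
                                 defs = pap_block_defs()) {
  stopifnot(n_members >= 0, n_decoys >= 0)
  n_dev <- length(degradation_spec)
  if (n_dev > n_members) stop("more deviants than members", call. = FALSE)
  for (d in degradation_spec) {
    if (any(!d$drop_blocks %in% 1:5)) {
      stop("degradation references block outside 1..5", call. = FALSE)
    }
  }
  with_seed(child_seed(seed, 1L), {
    ## template: random scaffold with concrete block words at random spacings
    block_words <- lapply(defs, function(def) {
      vapply(def$positions, function(set) sample(set, 1L), character(1))
    })
    block_len <- vapply(block_words, length, integer(1))
    n_blocks <- length(block_words)
    spacer_len <- sample(15:35, n_blocks + 1L, replace = TRUE)
    template <- character(0)
    block_spans <- list()
    for (b in seq_len(n_blocks)) {
      template <- c(template, sample(AA, spacer_len[b], replace = TRUE))
      st <- length(template) + 1L
      template <- c(template, block_words[[b]])
      block_spans[[b]] <- st:(st + block_len[b] - 1L)
    }
    template <- c(template, sample(AA, spacer_len[n_blocks + 1L], replace = TRUE))
    L <- length(template)
    half <- ceiling(L / 2)
    block_pos <- unlist(block_spans)

    mutate_member <- function() {
      s <- template
      off_block <- setdiff(seq_len(L), block_pos)
      mut <- off_block[stats::runif(length(off_block)) < sub_prob]
      if (length(mut) > 0L) {
        s[mut] <- vapply(s[mut], function(r) sample(setdiff(AA, r), 1L),
                         character(1))
      }
      s
    }
    apply_deviation <- function(s, dev) {
      for (b in dev$drop_blocks) {
        repeat { # degrade the block; re-draw if the motif survives by chance
          s[block_spans[[b]]] <- sample(AA, block_len[b], replace = TRUE)
          word <- s[block_spans[[b]]]
          still <- all(mapply(function(r, set) r %in% set, word,
                              defs[[b]]$positions))
          if (!still) break
        }
      }
      if (isTRUE(dev$y2f)) {
        sp <- block_spans[[2L]]
        s[sp[length(sp)]] <- "F"
      }
      dh <- dev$degrade_half %||% "none"
      if (dh != "none") {
        zone <- if (dh == "C") (half + 1L):L else seq_len(half)
        zone <- setdiff(zone, block_pos)
        s[zone] <- sample(AA, length(zone), replace = TRUE)
      }
      s
    }

    ## re-randomize any scaffold window that matches a block by chance, so
    ## blocks_present in the truth table is exact for every seed
    scrub_member <- function(s, kept_blocks) {
      kept_spans <- lapply(kept_blocks, function(b) block_spans[[b]])
      kept_starts <- vapply(kept_spans, `[[`, integer(1), 1L)
      for (iter in seq_len(50L)) {
        spurious <- integer(0)
        for (def in defs) {
          for (mt in raw_block_matches(s, def, allow_substitutions = TRUE)) {
            planted <- def$block_index %in% kept_blocks &&
              mt$start == block_spans[[def$block_index]][1L]
            if (!planted) {
              spurious <- c(spurious,
                            mt$start:(mt$start + length(def$positions) - 1L))
            }
          }
        }
        spurious <- setdiff(spurious, unlist(kept_spans))
        if (length(spurious) == 0L) break
        s[spurious] <- sample(AA, length(spurious), replace = TRUE)
      }
      s
    }

    ids <- sprintf("PAP%02d", seq_len(n_members))
    n_complete <- n_members - n_dev
    truth <- list()
    members <- character(0)
    for (k in seq_len(n_members)) {
      s <- mutate_member()
      if (k > n_complete) {
        dev <- degradation_spec[[k - n_complete]]
        s <- apply_deviation(s, dev)
        present <- setdiff(1:5, dev$drop_blocks)
        subs <- if (isTRUE(dev$y2f)) "block2:Y5F" else ""
        label <- dev$label
      } else {
        if (k > n_complete - n_y2f_complete) {
          s <- apply_deviation(s, list(drop_blocks = integer(0), y2f = TRUE,
                                       degrade_half = "none"))
          subs <- "block2:Y5F"
        } else {
          subs <- ""
        }
        present <- 1:5
        label <- "complete"
      }
      s <- scrub_member(s, present)
      members[ids[k]] <- paste(s, collapse = "")
      truth[[k]] <- tibble::tibble(
        id = ids[k], role = if (k > n_complete) "deviant" else "member",
        blocks_present = paste(present, collapse = ","),
        substitutions = subs, label = label
      )
    }

    decoys <- character(0)
    if (n_decoys > 0L) {
      src <- if (n_members > 0L) members else
        vapply(seq_len(1L), function(i) rand_protein(L), character(1))
      for (k in seq_len(n_decoys)) {
        base <- chars(src[[((k - 1L) %% length(src)) + 1L]])
        id <- sprintf("DECOY%02d", k)
        decoys[id] <- paste(sample(base, length(base)), collapse = "")
        truth[[length(truth) + 1L]] <- tibble::tibble(
          id = id, role = "decoy", blocks_present = "",
          substitutions = "", label = "shuffled"
        )
      }
    }

    list(
      proteome = c(members, decoys),
      seed_msa = members,
      truth = dplyr::bind_rows(truth),
      params = list(n_members = n_members, n_decoys = n_decoys,
                    n_y2f_complete = n_y2f_complete, seed = seed,
                    template_length = L, sub_prob = sub_prob)
    )
  })
}

#' Simulate promoters with planted cis-elements
#'
#' Uniform-background promoters with concrete element words (drawn
#' uniformly from the pattern's degeneracy expansion) planted at random
#' non-overlapping positions and strands. By default the background is
#' scrubbed of accidental element matches (windows matching any element
#' on either strand are re-randomized), so the planted positions are
#' exactly the matches a scanner should find; `scrub = FALSE` keeps the
#' raw background, whose chance-match rate follows the degeneracy count
#' per window.
#'
#' @param n number of promoters. Default 25.
#' @param plant tibble with columns `promoter` (index in 1..n) and
#'   `element` (name in `defs`): one planted element per row. Default:
#'   one P1BS in each of the first 18 promoters.
#' @param length promoter length. Default 3000 (3 kb upstream).
#' @param seed integer seed.
#' @param defs element definitions.
#' @param scrub re-randomize accidental background matches. Default TRUE.
#' @return list: `promoters` (named character vector), `truth` (tibble:
#'   `promoter_id`, `element`, `start`, `strand`, `word`), `params`.
#' @export
make_promoters <- function(n = 25,
                           plant = tibble::tibble(
                             promoter = 1:18, element = "P1BS"
                           ),
                           length = 3000, seed = 1,
                           defs = cis_element_defs(), scrub = TRUE) {
  stopifnot(n >= 0)
  if (nrow(plant) > 0L && any(!plant$element %in% defs$name)) {
    stop("planted element not in definitions", call. = FALSE)
  }
  expand_word <- function(pattern) {
    paste(vapply(chars(pattern), function(b) sample(IUPAC_DNA[[b]], 1L),
                 character(1)), collapse = "")
  }
  with_seed(child_seed(seed, 2L), {
    ids <- sprintf("PROM%02d", seq_len(n))
    promoters <- character(0)
    truth <- list()
    for (k in seq_len(n)) {
      seq_c <- chars(rand_dna(length))
      rows <- plant[plant$promoter == k, , drop = FALSE]
      occupied <- integer(0)
      if (nrow(rows) > 0L) {
        for (r in seq_len(nrow(rows))) {
          pat <- defs$pattern[defs$name == rows$element[r]]
          w <- nchar(pat)
          word <- expand_word(pat)
          strand <- sample(c("+", "-"), 1L)
          free <- setdiff(seq_len(length - w + 1L),
                          unlist(lapply(occupied, function(o) (o - w + 1L):(o + w - 1L))))
          if (base::length(free) == 0L) {
            stop("cannot place planted elements without overlap", call. = FALSE)
          }
          st <- pick1(free)
          palindromic <- iupac_revcomp(pat) == pat
          if (palindromic) strand <- "+" # reported once, on '+'
          inserted <- if (strand == "+") word else revcomp(word)
          seq_c[st:(st + w - 1L)] <- chars(inserted)
          occupied <- c(occupied, st:(st + w - 1L))
          truth[[base::length(truth) + 1L]] <- tibble::tibble(
            promoter_id = ids[k], element = rows$element[r],
            start = st, strand = strand, word = inserted
          )
        }
      }
      if (scrub) {
        planted_here <- dplyr::bind_rows(truth)
        planted_here <- planted_here[planted_here$promoter_id == ids[k], ,
                                     drop = FALSE]
        for (iter in seq_len(200L)) {
          hits <- scan_promoter(paste(seq_c, collapse = ""), defs,
                                promoter_id = ids[k])
          keyed <- paste(hits$element, hits$start, hits$strand)
          want <- if (nrow(planted_here) > 0L) {
            paste(planted_here$element, planted_here$start, planted_here$strand)
          } else {
            character(0)
          }
          spurious <- hits[!(keyed %in% want), , drop = FALSE]
          if (nrow(spurious) == 0L) break
          for (r in seq_len(nrow(spurious))) {
            w <- nchar(spurious$matched_word[r])
            span <- spurious$start[r]:(spurious$start[r] + w - 1L)
            span <- setdiff(span, occupied)
            if (base::length(span) > 0L) {
              seq_c[span] <- sample(DNA, base::length(span), replace = TRUE)
            }
          }
        }
      }
      promoters[ids[k]] <- paste(seq_c, collapse = "")
    }
    list(
      promoters = promoters,
      truth = dplyr::bind_rows(truth) %||% tibble::tibble(),
      params = list(n = n, length = length, seed = seed, scrub = scrub)
    )
  })
}

#' Evolve a protein alignment down a tree
#'
#' The root sequence is uniform over the 20 residues; along each branch,
#' each site substitutes with the branch's probability to a uniformly
#' chosen different residue. Produces an ungapped alignment, one row per
#' tip.
#'
#' @param tree an `ape::phylo` (binary).
#' @param n_columns number of alignment columns.
#' @param subst_prob per-branch substitution probability in \[0, 1):
#'   scalar, or a vector along `tree$edge`.
#' @param seed integer seed.
#' @return list: `msa` (named character vector of tip rows), `truth`
#'   (the tree and parameters).
#' @export
evolve_msa <- function(tree, n_columns, subst_prob, seed = 1) {
  stopifnot(inherits(tree, "phylo"), n_columns >= 1)
  n_edge <- nrow(tree$edge)
  p <- if (length(subst_prob) == 1L) rep(subst_prob, n_edge) else subst_prob
  stopifnot(length(p) == n_edge, all(p >= 0), all(p < 1))
  with_seed(child_seed(seed, 3L), {
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    seqs <- vector("list", n_tip + tree$Nnode)
    seqs[[root]] <- sample(AA, n_columns, replace = TRUE)
    ## preorder: parents appear before children in reorder(tree)
    tr <- ape::reorder.phylo(tree, "cladewise")
    eo <- match(paste(tr$edge[, 1], tr$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
    for (k in seq_len(n_edge)) {
      parent <- tr$edge[k, 1L]
      child <- tr$edge[k, 2L]
      s <- seqs[[parent]]
      hit <- which(stats::runif(n_columns) < p[eo[k]])
      if (length(hit) > 0L) {
        s[hit] <- vapply(s[hit], function(r) sample(setdiff(AA, r), 1L),
                         character(1))
      }
      seqs[[child]] <- s
    }
    msa <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""),
                  character(1))
    names(msa) <- tree$tip.label
    list(msa = msa,
         truth = list(tree = tree, subst_prob = p, n_columns = n_columns,
                      seed = seed))
  })
}

#' Simulate a structured genotype-phenotype association panel
#'
#' Genotypes are drawn per subpopulation under Hardy-Weinberg from
#' subpopulation-specific allele frequencies; the trait is a
#' subpopulation mean shift plus an additive causal-SNP effect plus
#' Gaussian noise. The causal effect size is solved in closed form so
#' that the causal SNP's theoretical *within-structure* share of the
#' total trait variance equals `pve_theoretical` percent — the partial
#' variance share that a structure-adjusted association model estimates;
#' the between-subpopulation component of the SNP's variance is absorbed
#' by the structure covariates.
#'
#' @param n_samples panel size. Default 92, a typical candidate-gene
#'   association panel.
#' @param n_snps number of SNPs. Default 100.
#' @param causal_spec list with `snp` (index or NULL for no causal SNP)
#'   and `pve_theoretical` in \[0, 100).
#' @param structure_spec list with `proportions` (subpopulation weights),
#'   `mean_shifts` (per-subpopulation trait shifts), `freq_spread`
#'   (half-width of the per-subpopulation allele-frequency deviation).
#' @param noise_sd residual trait standard deviation. Default 1.
#' @param seed integer seed.
#' @return list: `geno` (samples x SNPs matrix, 0/1/2), `trait`,
#'   `covariates` (subpopulation indicator columns, the Q-matrix
#'   analogue), `truth` (tibble + list: causal snp, beta, theoretical
#'   variances, subpopulation labels, per-subpopulation frequencies).
#' @export
make_geno_pheno <- function(n_samples = 92, n_snps = 100,
                            causal_spec = list(snp = 1L, pve_theoretical = 25),
                            structure_spec = list(
                              proportions = c(0.4, 0.35, 0.25),
                              mean_shifts = c(-0.6, 0, 0.6),
                              freq_spread = 0.15
                            ),
                            noise_sd = 1, seed = 1) {
  pve <- causal_spec$pve_theoretical %||% 0
  if (pve < 0 || pve > 100) stop("pve_theoretical must lie in [0, 100]", call. = FALSE)
  w <- structure_spec$proportions / sum(structure_spec$proportions)
  k_pop <- length(w)
  shifts <- structure_spec$mean_shifts
  stopifnot(length(shifts) == k_pop)
  spread <- structure_spec$freq_spread %||% 0.15

  with_seed(child_seed(seed, 4L), {
    pop <- sample(seq_len(k_pop), n_samples, replace = TRUE, prob = w)
    base_f <- stats::runif(n_snps, 0.1, 0.9)
    pop_f <- sapply(seq_len(k_pop), function(kp) {
      pmin(pmax(base_f + stats::runif(n_snps, -spread, spread), 0.02), 0.98)
    }) # n_snps x k_pop
    geno <- matrix(NA_real_, n_samples, n_snps,
                   dimnames = list(sprintf("ACC%03d", seq_len(n_samples)),
                                   sprintf("snp%04d", seq_len(n_snps))))
    for (kp in seq_len(k_pop)) {
      idx <- which(pop == kp)
      if (length(idx) == 0L) next
      draws <- vapply(seq_len(n_snps), function(s) {
        stats::rbinom(length(idx), 2L, pop_f[s, kp])
      }, numeric(length(idx)))
      geno[idx, ] <- matrix(draws, nrow = length(idx), ncol = n_snps)
    }

    causal <- causal_spec$snp
    beta <- 0
    v_within <- NA_real_
    v_between <- NA_real_
    mu_shift <- sum(w * shifts)
    var_struct <- sum(w * shifts^2) - mu_shift^2
    if (!is.null(causal) && pve > 0) {
      ## the planted PVE is the *within-structure* (partial) variance
      ## share — the quantity a structure-adjusted association model
      ## estimates; the between-subpopulation part of the SNP's variance
      ## is absorbed by the covariates
      f <- pop_f[causal, ]
      v_within <- sum(w * 2 * f * (1 - f))
      v_between <- sum(w * (2 * f)^2) - sum(w * 2 * f)^2
      if (v_within <= 0) stop("infeasible PVE: causal SNP monomorphic", call. = FALSE)
      if (pve >= 100) {
        if (var_struct > 0 || noise_sd > 0 || v_between > 0) {
          stop("PVE 100 requires zero structure and noise", call. = FALSE)
        }
        beta <- 1
      } else {
        denom <- 100 * v_within - pve * (v_within + v_between)
        if (denom <= 0) {
          stop("infeasible PVE: exceeds the within-structure variance bound",
               call. = FALSE)
        }
        beta <- sqrt(pve * (var_struct + noise_sd^2) / denom)
      }
    }
    g_causal <- if (is.null(causal)) 0 else geno[, causal]
    trait <- shifts[pop] + beta * g_causal +
      stats::rnorm(n_samples, 0, noise_sd)

    Q <- matrix(0, n_samples, max(k_pop - 1L, 0L))
    for (kp in seq_len(k_pop - 1L)) Q[, kp] <- as.numeric(pop == kp)
    if (ncol(Q) > 0L) colnames(Q) <- paste0("Q", seq_len(k_pop - 1L))
    if (ncol(Q) == 0L) Q <- NULL

    list(
      geno = geno, trait = trait, covariates = Q,
      truth = list(
        causal_snp = if (is.null(causal)) NA_character_ else colnames(geno)[causal],
        beta = beta, pve_theoretical = pve,
        var_genetic = if (is.null(causal) || pve == 0) 0 else beta^2 * v_within,
        var_genetic_between = if (is.null(causal) || pve == 0) 0 else
          beta^2 * v_between,
        var_structure = var_struct, var_noise = noise_sd^2,
        pop = pop, pop_freq = pop_f, proportions = w,
        mean_shifts = shifts, seed = seed
      )
    )
  })
}

#' Simulate a replicated qPCR Ct table
#'
#' Reference-gene Ct values are a constant plus Gaussian replicate noise;
#' target Ct values add the delta-Ct implied by the planted fold change
#' (condition mode) or planted relative expression (genotype mode).
#'
#' @param true_fold_change treated-vs-control fold change (condition
#'   mode); ignored when `genotypes` is given.
#' @param genotypes optional named numeric vector of planted relative
#'   expression values (2^-dCt) per genotype; switches to genotype mode.
#' @param replicate_sd Gaussian Ct noise SD. Default 0.2 cycles.
#' @param n_reps replicates per cell. Default 3.
#' @param ref_ct reference-gene mean Ct. Default 20.
#' @param base_dct control-condition delta-Ct. Default 3.
#' @param seed integer seed.
#' @return list: `table` (a Ct tibble suitable for [delta_delta_ct()] or
#'   [relative_expression_2dct()]), `truth`.
#' @export
make_ct_table <- function(true_fold_change = 4, genotypes = NULL,
                          replicate_sd = 0.2, n_reps = 3,
                          ref_ct = 20, base_dct = 3, seed = 1) {
  with_seed(child_seed(seed, 5L), {
    noise <- function(k) stats::rnorm(k, 0, replicate_sd)
    if (is.null(genotypes)) {
      if (true_fold_change <= 0) stop("fold change must be > 0", call. = FALSE)
      dct_treated <- base_dct - log2(true_fold_change)
      rows <- list()
      for (cond in c("control", "treated")) {
        dct <- if (cond == "control") base_dct else dct_treated
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sample_id = paste0(cond, "_", seq_len(n_reps)),
          condition = cond, gene = "reference",
          replicate = seq_len(n_reps), ct = ref_ct + noise(n_reps)
        )
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sample_id = paste0(cond, "_", seq_len(n_reps)),
          condition = cond, gene = "target",
          replicate = seq_len(n_reps), ct = ref_ct + dct + noise(n_reps)
        )
      }
      list(table = dplyr::bind_rows(rows),
           truth = list(fold_change = true_fold_change,
                        replicate_sd = replicate_sd, seed = seed))
    } else {
      if (any(genotypes <= 0)) stop("expression values must be > 0", call. = FALSE)
      rows <- purrr::imap(genotypes, function(expr, g) {
        dct <- -log2(expr)
        dplyr::bind_rows(
          tibble::tibble(genotype_id = g, gene = "reference",
                         replicate = seq_len(n_reps),
                         ct = ref_ct + noise(n_reps)),
          tibble::tibble(genotype_id = g, gene = "target",
                         replicate = seq_len(n_reps),
                         ct = ref_ct + dct + noise(n_reps))
        )
      })
      list(table = dplyr::bind_rows(rows),
           truth = list(expression = genotypes,
                        replicate_sd = replicate_sd, seed = seed))
    }
  })
}

#' Simulate gene models (paired genomic and CDS sequences)
#'
#' Unique exon segments separated by random introns, optionally with
#' canonical GT..AG splice sites. Exon segments are re-drawn until each is
#' unique within the genomic sequence, the regime in which structures are
#' recoverable from a cDNA-genomic comparison.
#'
#' @param n number of genes.
#' @param exon_count_range inclusive range of exon counts. Default
#'   c(2, 12).
#' @param exon_length_range inclusive range of exon lengths (>= 10).
#' @param intron_length_range inclusive range of intron lengths.
#' @param splice_sites write GT..AG intron boundaries. Default TRUE.
#' @param seed integer seed.
#' @return list: `genes` (list per gene: `gene_id`, `genomic`, `cds`),
#'   `truth` (tibble: `gene_id`, `exon_count`, `spans` as
#'   "start-end;start-end").
#' @export
make_gene_models <- function(n = 5, exon_count_range = c(2, 12),
                             exon_length_range = c(20, 60),
                             intron_length_range = c(30, 120),
                             splice_sites = TRUE, seed = 1) {
  stopifnot(exon_length_range[1] >= 10)
  with_seed(child_seed(seed, 6L), {
    genes <- list()
    truth <- list()
    for (k in seq_len(n)) {
      n_exon <- pick1(exon_count_range[1]:exon_count_range[2])
      for (attempt in seq_len(100L)) {
        exons <- vapply(seq_len(n_exon), function(i) {
          rand_dna(pick1(exon_length_range[1]:exon_length_range[2]))
        }, character(1))
        introns <- vapply(seq_len(n_exon - 1L), function(i) {
          len <- pick1(intron_length_range[1]:intron_length_range[2])
          body <- rand_dna(len - 4L)
          if (splice_sites) paste0("GT", body, "AG") else rand_dna(len)
        }, character(1))
        ## disambiguate the splice boundaries so the spliced embedding is
        ## unique: the base after each exon end (intron start) must differ
        ## from the next exon's first base, and the base before each exon
        ## start (intron end) from the previous exon's last base
        for (i in seq_len(n_exon - 1L)) {
          i_first <- substr(introns[i], 1L, 1L)
          if (substr(exons[i + 1L], 1L, 1L) == i_first) {
            substr(exons[i + 1L], 1L, 1L) <-
              sample(setdiff(DNA, i_first), 1L)
          }
          i_last <- substr(introns[i], nchar(introns[i]), nchar(introns[i]))
          if (substr(exons[i], nchar(exons[i]), nchar(exons[i])) == i_last) {
            substr(exons[i], nchar(exons[i]), nchar(exons[i])) <-
              sample(setdiff(DNA, i_last), 1L)
          }
        }
        flank5 <- rand_dna(30)
        flank3 <- rand_dna(30)
        pieces <- character(0)
        spans <- matrix(0L, n_exon, 2L)
        pos <- nchar(flank5)
        pieces <- flank5
        for (i in seq_len(n_exon)) {
          spans[i, ] <- c(pos + 1L, pos + nchar(exons[i]))
          pieces <- c(pieces, exons[i])
          pos <- pos + nchar(exons[i])
          if (i < n_exon) {
            pieces <- c(pieces, introns[i])
            pos <- pos + nchar(introns[i])
          }
        }
        pieces <- c(pieces, flank3)
        genomic <- paste(pieces, collapse = "")
        ## each exon must occur exactly once in the genomic sequence
        unique_ok <- all(vapply(exons, function(e) {
          length(regex_starts(genomic, e)) == 1L
        }, logical(1)))
        if (unique_ok) break
      }
      gene_id <- sprintf("GENE%02d", k)
      genes[[gene_id]] <- list(gene_id = gene_id, genomic = genomic,
                               cds = paste(exons, collapse = ""))
      truth[[k]] <- tibble::tibble(
        gene_id = gene_id, exon_count = n_exon,
        spans = paste(sprintf("%d-%d", spans[, 1], spans[, 2]), collapse = ";")
      )
    }
    list(genes = genes, truth = dplyr::bind_rows(truth))
  })
}
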