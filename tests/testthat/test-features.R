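test_that("molecular weight matches the residue-mass summation", {
  expect_equal(molecular_weight("G"), 75.07, tolerance = 1e-4)
  expect_equal(molecular_weight("GG"), 132.12, tolerance = 1e-4)
  expect_error(molecular_weight(""), "non-empty")
  expect_error(molecular_weight("GXG"), "position 2")
})

test_that("MW is additive up to one water", {
  set.seed(5)
  for (k in 1:25) {
    a <- random_peptide(sample(1:30, 1))
    b <- random_peptide(sample(1:30, 1))
    expect_equal(molecular_weight(paste0(a, b)),
                 molecular_weight(a) + molecular_weight(b) - 18.01528,
                 tolerance = 1e-9)
  }
})

test_that("net charge behaves at the pH extremes and decreases in pH", {
  set.seed(9)
  for (k in 1:10) {
    s <- random_peptide(sample(5:40, 1))
    cs <- strsplit(s, "")[[1]]
    ## at pH -> 0 all basic groups are protonated, acidic ones neutral
    expect_equal(net_charge(s, 0), 1 + sum(cs %in% c("H", "K", "R")),
                 tolerance = 0.02)
    ph <- seq(1, 13, by = 0.5)
    expect_true(all(diff(net_charge(s, ph)) < 0))
  }
})

test_that("pI agrees with an independent bisection oracle", {
  expect_lt(isoelectric_point("D"), 7)
  expect_gt(isoelectric_point("K"), 7)
  set.seed(21)
  for (k in 1:100) {
    s <- random_peptide(sample(5:60, 1))
    expect_equal(isoelectric_point(s), oracle_pi(s), tolerance = 0.01)
  }
})

test_that("MW agrees with an independent summation oracle", {
  set.seed(22)
  for (k in 1:100) {
    s <- random_peptide(sample(5:60, 1))
    expect_equal(molecular_weight(s), oracle_mw(s), tolerance = 0.01)
  }
})

test_that("sequon scan finds N-X(not P)-[S/T] and nothing else", {
  expect_equal(glyco_sequons("NGS"), 1L)
  expect_equal(glyco_sequons("NPS"), integer(0))
  expect_equal(glyco_sequons("ANQTNAS"), c(2L, 5L))
  ## brute-force window check on random peptides
  set.seed(31)
  for (k in 1:20) {
    s <- random_peptide(30)
    cs <- strsplit(s, "")[[1]]
    want <- which(vapply(1:28, function(i) {
      cs[i] == "N" && cs[i + 1] != "P" && cs[i + 2] %in% c("S", "T")
    }, logical(1)))
    expect_equal(glyco_sequons(s), as.integer(want))
  }
})

test_that("promoter scanning matches the degeneracy expansion on both strands", {
  defs <- cis_element_defs()
  p1bs <- defs[defs$name == "P1BS", ]
  ## spec words
  expect_equal(nrow(scan_promoter("GAATATCC", p1bs)), 1L)
  expect_equal(scan_promoter("GAATATCC", p1bs)$strand, "+")
  expect_equal(nrow(scan_promoter("GGGGGGGG", defs)), 0L)
  ## all 16 words of GNATATNC match
  for (b1 in c("A", "C", "G", "T")) {
    for (b2 in c("A", "C", "G", "T")) {
      w <- paste0("G", b1, "ATAT", b2, "C")
      expect_equal(nrow(scan_promoter(w, p1bs)), 1L)
    }
  }
  ## ambiguous base in the promoter never matches
  expect_equal(nrow(scan_promoter("GNATATCC", p1bs)), 0L)
  ## non-palindromic element is found on the minus strand
  wbox <- defs[defs$name == "Wbox", ]
  hit <- scan_promoter("AAAGTCAAAAA", wbox) # revcomp TTGACT at 3
  expect_equal(hit$strand, "-")
  expect_equal(hit$start, 3L)
})

test_that("strand symmetry: reverse-complementing the promoter mirrors hits", {
  set.seed(41)
  defs <- cis_element_defs()
  for (k in 1:10) {
    prom <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                  collapse = "")
    fwd <- scan_promoter(prom, defs)
    rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(prom, "")[[1]])),
                collapse = "")
    rev_hits <- scan_promoter(rc, defs)
    n <- nchar(prom)
    ## map reverse hits back to the original coordinates
    mapped <- sort(n - (rev_hits$start + nchar(rev_hits$matched_word) - 1L) + 1L)
    expect_equal(mapped, sort(fwd$start))
  }
})

test_that("gene structure is recovered by spliced embedding", {
  ## two unique >= 10-mers split by an intron
  e1 <- "ACGTACGTCCAGGATTACAG"
  e2 <- "TTGCACGGATCGATTTCGAT"
  genomic <- paste0("GGGGGAA", e1, "GTAAACCCTTTAG", e2, "TTTTT")
  st <- infer_gene_structure(paste0(e1, e2), genomic)
  expect_equal(st$exon_count, 2L)
  expect_equal(st$exons$start, c(8, 41))
  expect_equal(st$exons$end, c(27, 60))
  ## contiguous CDS: single exon
  st1 <- infer_gene_structure(e1, genomic)
  expect_equal(st1$exon_count, 1L)
  ## not embeddable
  expect_error(infer_gene_structure("ACGTACGTAAAAAAAACCCCCCGGGGGG", genomic),
               "not embeddable")
  ## strict splice mode accepts the GT..AG intron above
  st2 <- infer_gene_structure(paste0(e1, e2), genomic,
                              strict_splice_sites = TRUE)
  expect_equal(st2$exon_count, 2L)
})

test_that("planted gene structures round-trip exactly, including 12 exons", {
  gm <- make_gene_models(n = 4, exon_count_range = c(2, 12), seed = 19)
  for (g in gm$genes) {
    st <- infer_gene_structure(g$cds, g$genomic, gene_id = g$gene_id)
    want <- gm$truth[gm$truth$gene_id == g$gene_id, ]
    expect_equal(st$exon_count, want$exon_count)
    got_spans <- paste(sprintf("%d-%d", st$exons$start, st$exons$end),
                       collapse = ";")
    expect_equal(got_spans, want$spans)
    ## concatenated exon sequence equals the CDS
    gen <- strsplit(g$genomic, "")[[1]]
    concat <- paste(unlist(lapply(seq_len(nrow(st$exons)), function(i) {
      gen[st$exons$start[i]:st$exons$end[i]]
    })), collapse = "")
    expect_equal(concat, g$cds)
  }
  ## a deliberately 12-exon gene
  gm12 <- make_gene_models(n = 1, exon_count_range = c(12, 12), seed = 23)
  g <- gm12$genes[[1]]
  expect_equal(infer_gene_structure(g$cds, g$genomic)$exon_count, 12L)
})

test_that("protein annotation table joins external predictor calls", {
  prots <- c(P1 = "MKNGSWHD", P2 = "GGGG")
  ext <- tibble::tibble(protein_id = "P1", signalp = "Y")
  ann <- annotate_proteins(prots, external = ext)
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$n_sequons, c(1L, 0L))
  expect_equal(ann$signalp, c("Y", NA))
  expect_equal(ann$mw[2], molecular_weight("GGGG"))
})

test_that("cis-element hits export to BED with 0-based half-open coordinates", {
  hits <- scan_promoter("GAATATCCAA", cis_element_defs(),
                        promoter_id = "PROM01")
  tf <- tempfile(fileext = ".bed")
  write_cis_bed(hits, tf)
  bed <- read.delim(tf, header = FALSE)
  expect_equal(bed$V2[1], 0L)
  expect_equal(bed$V3[1], 8L)
  expect_equal(bed$V4[1], "P1BS")
})
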