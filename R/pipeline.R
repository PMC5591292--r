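#' Default pipeline configuration
#'
#' All thresholds with their documented defaults: 10-bit profile score,
#' MAF 0.05, FDR 0.05, both-strand cis-element scanning, 1000 bootstrap
#' replicates, seed 1.
#'
#' @param ... overrides of the listed fields.
#' @return a named list (class `pap_config`).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    out_dir = NULL,
    seed_msa = NULL,            # path to aligned FASTA or named vector
    proteome = NULL,            # path to protein FASTA or named vector
    promoters = NULL,           # path to DNA FASTA or named vector
    gene_models = NULL,         # list of list(gene_id, genomic, cds)
    phylo_alignment = NULL,     # aligned FASTA/named vector (refs + queries)
    reference_labels = NULL,    # named vector leaf -> subgroup
    score_threshold = 10,
    min_maf = 0.05,
    fdr = 0.05,
    both_strands = TRUE,
    bootstrap_replicates = 1000,
    allow_substitutions = TRUE,
    seed = 1,
    stages = c("profile", "scan", "screen", "annotate", "phylo")
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(ov)] <- ov
  structure(cfg, class = "pap_config")
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pap_config"))
  if (is.null(cfg$out_dir)) stop("config: out_dir is required", call. = FALSE)
  for (field in c("seed_msa", "proteome", "promoters")) {
    v <- cfg[[field]]
    if (is.character(v) && length(v) == 1L && is.null(names(v)) &&
        !file.exists(v)) {
      stop("config: ", field, " path does not exist: ", v, call. = FALSE)
    }
  }
  if (cfg$min_maf < 0 || cfg$min_maf >= 0.5) {
    stop("config: min_maf out of range", call. = FALSE)
  }
  if (cfg$fdr <= 0 || cfg$fdr >= 1) stop("config: fdr out of range", call. = FALSE)
  if (cfg$bootstrap_replicates < 1) {
    stop("config: bootstrap_replicates must be >= 1", call. = FALSE)
  }
  invisible(cfg)
}

as_named_seqs <- function(x, type) {
  if (is.character(x) && length(x) == 1L && is.null(names(x))) {
    if (type == "AA") read_protein_fasta(x) else read_dna_fasta(x)
  } else {
    x
  }
}

#' Run the family-discovery pipeline
#'
#' Executes the requested stages in dependency order — profile build,
#' proteome scan, motif screen, feature annotation, phylogenetic subgroup
#' assignment — writing per-stage TSVs, a merged family table (one row per
#' scan hit: score, blocks, architecture, verdict, mw, pi, sequons,
#' cis-element counts, subgroup), and a JSON run manifest recording
#' parameters, seed and input checksums. A stage failure aborts with an
#' error naming the stage.
#'
#' @param config a `pap_config` from [pipeline_config()].
#' @return invisibly, a list with the per-stage results, the merged
#'   `family_table`, and the `manifest`.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  warnings_log <- character(0)
  log_stage <- function(stage) {
    message(sprintf("[papfam] stage %-10s %s", stage, format(Sys.time(), "%H:%M:%S")))
  }
  run_stage <- function(stage, expr) {
    log_stage(stage)
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log, paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
  }
  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  stages <- config$stages
  proteome <- if (!is.null(config$proteome)) {
    as_named_seqs(config$proteome, "AA")
  }

  if ("profile" %in% stages) {
    results$profile <- run_stage("profile", {
      msa <- as_named_seqs(config$seed_msa, "AA")
      prof <- build_profile(msa)
      write_profile_json(prof, file.path(config$out_dir, "profile.json"))
      prof
    })
  }
  if ("scan" %in% stages) {
    results$hits <- run_stage("scan", {
      hits <- scan_proteome(results$profile, proteome,
                            score_threshold = config$score_threshold)
      write_tsv(hits, "scan_hits.tsv")
      hits
    })
  }
  if ("screen" %in% stages) {
    results$screen <- run_stage("screen", {
      scr <- screen_candidates(proteome, results$hits,
                               allow_substitutions = config$allow_substitutions,
                               score_threshold = config$score_threshold)
      rep <- screen_report(scr)
      write_tsv(rep, "screen.tsv")
      write_tsv(attr(rep, "tally"), "screen_tally.tsv")
      rep
    })
  }
  if ("annotate" %in% stages) {
    results$annotation <- run_stage("annotate", {
      ids <- results$hits$protein_id
      ann <- annotate_proteins(proteome[ids])
      if (!is.null(config$promoters)) {
        proms <- as_named_seqs(config$promoters, "DNA")
        defs <- cis_element_defs()
        defs$scan_both_strands <- config$both_strands
        cis <- purrr::imap_dfr(proms, function(sq, id) {
          scan_promoter(sq, defs, promoter_id = id)
        })
        write_tsv(cis, "cis_hits.tsv")
        results$cis <- cis
      }
      if (!is.null(config$gene_models)) {
        gs <- purrr::map_dfr(config$gene_models, function(g) {
          st <- infer_gene_structure(g$cds, g$genomic, gene_id = g$gene_id)
          tibble::tibble(gene_id = g$gene_id, exon_count = st$exon_count)
        })
        write_tsv(gs, "gene_structure.tsv")
        results$gene_structure <- gs
      }
      write_tsv(ann, "annotation.tsv")
      ann
    })
  }
  if ("phylo" %in% stages && !is.null(config$reference_labels) &&
      !is.null(config$phylo_alignment)) {
    results$subgroups <- run_stage("phylo", {
      aln <- as_named_seqs(config$phylo_alignment, "AA")
      if (length(unique(nchar(aln))) != 1L) {
        stop("phylo stage expects pre-aligned equal-length sequences")
      }
      tree <- bootstrap_support(aln,
                                n_replicates = config$bootstrap_replicates,
                                seed = config$seed)
      write_tree_newick(tree, file.path(config$out_dir, "tree.nwk"))
      asn <- assign_subgroups(tree, config$reference_labels)
      write_tsv(asn, "subgroups.tsv")
      asn
    })
  }

  ## merged family table: one row per scan hit
  family <- results$hits
  if (!is.null(results$screen)) {
    family <- dplyr::left_join(
      family, dplyr::select(results$screen, -dplyr::any_of("score_bits")),
      by = "protein_id"
    )
  }
  if (!is.null(results$annotation)) {
    family <- dplyr::left_join(family, results$annotation, by = "protein_id")
  }
  if (!is.null(results$cis)) {
    counts <- dplyr::count(results$cis, .data$promoter_id, .data$element)
    wide <- tidyr::pivot_wider(counts, names_from = "element",
                               values_from = "n", values_fill = 0L,
                               names_prefix = "cis_")
    family <- dplyr::left_join(family, wide,
                               by = c(protein_id = "promoter_id"))
  }
  if (!is.null(results$subgroups)) {
    family <- dplyr::left_join(
      family,
      dplyr::select(results$subgroups, protein_id = "query", "subgroup"),
      by = "protein_id"
    )
  }
  write_tsv(family, "family_table.tsv")
  results$family_table <- family

  checksum <- function(x) {
    if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
        file.exists(x)) {
      unname(tools::md5sum(x))
    } else if (!is.null(x)) {
      digest_chr(x)
    } else {
      NA_character_
    }
  }
  manifest <- list(
    package = "papfam",
    version = as.character(utils::packageVersion("papfam")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    parameters = config[c("score_threshold", "min_maf", "fdr",
                          "both_strands", "bootstrap_replicates",
                          "allow_substitutions")],
    stages = stages,
    input_checksums = list(
      seed_msa = checksum(config$seed_msa),
      proteome = checksum(config$proteome),
      promoters = checksum(config$promoters)
    ),
    warnings = warnings_log,
    n_hits = if (!is.null(results$hits)) nrow(results$hits) else 0L
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  results$manifest <- manifest
  invisible(results)
}

## order-stable checksum of an in-memory object (names + values)
digest_chr <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(names(x) %||% "", as.character(unlist(x))), tf)
  unname(tools::md5sum(tf))
}

#' Row-scale an expression matrix for heatmap display
#'
#' log2(RPM + 1) followed by per-row min-max scaling to \[0, 1\]; a
#' constant row scales to all zeros (documented convention). Row and
#' column order is preserved.
#'
#' @param rpm genes x tissues nonnegative matrix (RPM values).
#' @return matrix of the same dimensions, scaled.
#' @export
render_expression_matrix <- function(rpm) {
  rpm <- as.matrix(rpm)
  if (any(rpm < 0, na.rm = TRUE)) stop("RPM values must be nonnegative", call. = FALSE)
  lg <- log2(rpm + 1)
  t(apply(lg, 1L, function(r) {
    rng <- range(r)
    if (rng[1] == rng[2]) rep(0, length(r)) else (r - rng[1]) / (rng[2] - rng[1])
  }))
}

#' Heatmap of a row-scaled expression matrix
#'
#' @param rpm genes x tissues nonnegative matrix.
#' @param path optional file to save the figure to (via
#'   [ggplot2::ggsave()]).
#' @return a ggplot object.
#' @export
plot_expression_heatmap <- function(rpm, path = NULL) {
  scaled <- render_expression_matrix(rpm)
  df <- tibble::tibble(
    gene = factor(rep(rownames(scaled) %||% seq_len(nrow(scaled)),
                      times = ncol(scaled)),
                  levels = rev(rownames(scaled) %||% seq_len(nrow(scaled)))),
    tissue = factor(rep(colnames(scaled) %||% seq_len(ncol(scaled)),
                        each = nrow(scaled)),
                    levels = colnames(scaled) %||% seq_len(ncol(scaled))),
    value = as.vector(scaled)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$tissue, .data$gene,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "scaled\nlog2(RPM+1)") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 6, height = 8)
  p
}
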