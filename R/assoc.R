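#' Minor allele frequency of 0/1/2-coded SNP columns
#'
#' Missing calls are excluded from the denominator.
#'
#' @param geno samples x SNPs matrix or data frame with codes 0/1/2/NA.
#' @return numeric vector of per-SNP MAF.
#' @export
snp_maf <- function(geno) {
  geno <- as.matrix(geno)
  apply(geno, 2L, function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0L) return(NA_real_)
    f <- sum(g) / (2 * length(g))
    min(f, 1 - f)
  })
}

#' Filter SNPs by minor allele frequency
#'
#' SNPs with MAF below `min_maf` are removed; a SNP exactly at the
#' threshold is retained. The field's customary cutoff (and the default)
#' is 5 %.
#'
#' @param geno samples x SNPs matrix (codes 0/1/2/NA) with SNP column
#'   names.
#' @param min_maf minimum MAF in \[0, 0.5). Default 0.05.
#' @return the genotype matrix restricted to passing SNPs, with the
#'   per-SNP MAF of the kept SNPs as attribute `maf`.
#' @export
maf_filter <- function(geno, min_maf = 0.05) {
  if (!is.numeric(min_maf) || min_maf < 0 || min_maf >= 0.5) {
    stop("min_maf must lie in [0, 0.5)", call. = FALSE)
  }
  geno <- as.matrix(geno)
  maf <- snp_maf(geno)
  keep <- !is.na(maf) & maf >= min_maf
  out <- geno[, keep, drop = FALSE]
  attr(out, "maf") <- maf[keep]
  out
}

#' Candidate-gene marker-trait association (GLM with structure covariates)
#'
#' Per SNP, an ordinary least-squares fit of
#' `trait ~ covariates + additive SNP code` is compared against the
#' covariates-only fit: the SNP p-value is the F-test of the SNP term, the
#' proportion of phenotypic variance explained (PVE) is the partial R^2
#' `100 * (RSS_reduced - RSS_full) / TSS`, and q-values are
#' Benjamini-Hochberg adjusted over all tested SNPs. Population structure
#' enters through the covariate matrix (ancestry coefficients and/or
#' principal components); kinship-based mixed models are deliberately not
#' implemented — this is the fixed-effects simplification of the standard
#' structured-association model.
#'
#' Missing genotypes are mean-imputed per SNP by default
#' (`missing = "impute"`); alternatively samples with a missing call are
#' dropped per test (`missing = "drop"`).
#'
#' @param geno samples x SNPs matrix, additive codes 0/1/2 (copies of the
#'   alternative allele), NAs allowed.
#' @param trait numeric vector, one value per sample.
#' @param covariates optional numeric matrix/data frame of structure
#'   covariates (Q or PCs), samples in rows.
#' @param snp_info optional tibble keyed by `snp_id` with columns such as
#'   `chromosome`, `position`, `ref_allele`, `alt_allele`, joined onto the
#'   result.
#' @param missing `"impute"` (default) or `"drop"`.
#' @return a tibble of class `pap_assoc`, one row per SNP: `snp_id`,
#'   `effect` (per alt-allele copy), `p`, `pve` (percent), `q`,
#'   `high_allele` (`"alt"` if the alt allele raises the trait, `"ref"`
#'   otherwise), `n` used, plus joined `snp_info` columns.
#' @export
marker_trait_assoc <- function(geno, trait, covariates = NULL,
                               snp_info = NULL,
                               missing = c("impute", "drop")) {
  missing <- match.arg(missing)
  geno <- as.matrix(geno)
  n <- nrow(geno)
  stopifnot(length(trait) == n)
  if (is.null(colnames(geno))) {
    colnames(geno) <- paste0("snp", seq_len(ncol(geno)))
  }
  X0 <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    X0 <- cbind(X0, covariates)
    if (qr(X0)$rank < ncol(X0)) {
      stop("rank-deficient covariates", call. = FALSE)
    }
  }
  if (n <= ncol(X0) + 1L) {
    stop("too few samples for the covariate model", call. = FALSE)
  }

  tss <- sum((trait - mean(trait))^2)
  fit0 <- stats::lm.fit(X0, trait)
  rss0_all <- sum(fit0$residuals^2)

  rows <- purrr::map_dfr(seq_len(ncol(geno)), function(k) {
    g <- geno[, k]
    use <- rep(TRUE, n)
    if (anyNA(g)) {
      if (missing == "impute") {
        g[is.na(g)] <- mean(g, na.rm = TRUE)
      } else {
        use <- !is.na(g)
      }
    }
    yk <- trait[use]
    Xk0 <- X0[use, , drop = FALSE]
    gk <- g[use]
    if (stats::var(gk) == 0) {
      return(tibble::tibble(snp_id = colnames(geno)[k], effect = NA_real_,
                            p = NA_real_, pve = NA_real_,
                            high_allele = NA_character_,
                            n = sum(use)))
    }
    Xk <- cbind(Xk0, gk)
    fit <- stats::lm.fit(Xk, yk)
    rss_full <- sum(fit$residuals^2)
    rss_red <- if (all(use)) rss0_all else sum(stats::lm.fit(Xk0, yk)$residuals^2)
    tss_k <- if (all(use)) tss else sum((yk - mean(yk))^2)
    df_res <- length(yk) - ncol(Xk)
    f <- (rss_red - rss_full) / (rss_full / df_res)
    p <- stats::pf(f, 1, df_res, lower.tail = FALSE)
    beta <- unname(fit$coefficients[ncol(Xk)])
    tibble::tibble(
      snp_id = colnames(geno)[k],
      effect = beta,
      p = p,
      pve = 100 * (rss_red - rss_full) / tss_k,
      high_allele = ifelse(beta >= 0, "alt", "ref"),
      n = length(yk)
    )
  })
  rows$q <- stats::p.adjust(rows$p, method = "BH")
  rows <- dplyr::relocate(rows, "q", .after = "pve")
  if (!is.null(snp_info)) {
    stopifnot("snp_id" %in% names(snp_info))
    rows <- dplyr::left_join(rows, snp_info, by = "snp_id")
  }
  class(rows) <- c("pap_assoc", class(rows))
  rows
}

#' @importFrom generics tidy
#' @export
tidy.pap_assoc <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "pap_assoc")
  out
}

#' @importFrom generics glance
#' @export
glance.pap_assoc <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_snps = nrow(x),
    n_tested = sum(!is.na(x$p)),
    n_sig_p = sum(x$p <= alpha, na.rm = TRUE),
    n_sig_q = sum(x$q <= alpha, na.rm = TRUE),
    min_p = suppressWarnings(min(x$p, na.rm = TRUE)),
    max_pve = suppressWarnings(max(x$pve, na.rm = TRUE))
  )
}

#' Manhattan-style plot of association results
#'
#' @param object a `pap_assoc` tibble with `position` and `chromosome`
#'   columns (falls back to SNP index).
#' @param alpha significance line on the q scale. Default 0.05.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pap_assoc <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  df$x <- if ("position" %in% names(df)) df$position else seq_len(nrow(df))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = -log10(.data$p))) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = if ("position" %in% names(df)) "position (bp)" else "SNP index",
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
  if ("chromosome" %in% names(df)) {
    p <- p + ggplot2::facet_grid(cols = ggplot2::vars(.data$chromosome),
                                 scales = "free_x", space = "free_x")
  }
  thr <- suppressWarnings(max(df$p[df$q <= alpha], na.rm = TRUE))
  if (is.finite(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(thr), linetype = 2)
  }
  p
}

#' Read a 0/1/2-coded genotype matrix from TSV
#'
#' Expects samples in rows (first column = sample id) and SNPs in columns.
#'
#' @param path TSV path.
#' @return matrix with sample rownames and SNP colnames.
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  bad <- !is.na(m) & !(m %in% c(0, 1, 2))
  if (any(bad)) stop("genotype codes must be 0/1/2 or missing", call. = FALSE)
  m
}
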