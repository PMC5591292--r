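#' Relative expression by the delta-delta-Ct method
#'
#' Per condition, the replicate-level delta-Ct is Ct(target) -
#' Ct(reference), paired by replicate; the condition delta-Ct is its mean.
#' delta-delta-Ct = delta-Ct(treated) - delta-Ct(control) and fold change
#' = 2^(-delta-delta-Ct). The p-value is a two-sided Welch t-test on the
#' replicate-level delta-Ct values between conditions.
#'
#' @param table tibble with columns `condition` (values `control` /
#'   `treated`), `gene` (`target` / `reference`), `replicate`, `ct`.
#' @param alpha significance level for the flag. Default 0.05.
#' @return one-row tibble: `dct_control`, `dct_treated`, `ddct`,
#'   `fold_change`, `p`, `significant`.
#' @examples
#' ct <- tibble::tibble(
#'   condition = rep(c("control", "treated"), each = 2),
#'   gene = rep(c("target", "reference"), 2),
#'   replicate = 1L,
#'   ct = c(25, 20, 23, 20)
#' )
#' delta_delta_ct(ct) # ddct -2, fold 4
#' @export
delta_delta_ct <- function(table, alpha = 0.05) {
  need <- c("condition", "gene", "replicate", "ct")
  stopifnot(all(need %in% names(table)))
  if (any(table$ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  for (cond in c("control", "treated")) {
    sub <- table[table$condition == cond, ]
    if (nrow(sub) == 0L) stop("condition '", cond, "' missing", call. = FALSE)
    if (!"reference" %in% sub$gene) {
      stop("reference gene missing for condition '", cond, "'", call. = FALSE)
    }
    if (!"target" %in% sub$gene) {
      stop("target gene missing for condition '", cond, "'", call. = FALSE)
    }
  }
  dct <- replicate_dct(table)
  d_control <- dct$dct[dct$condition == "control"]
  d_treated <- dct$dct[dct$condition == "treated"]
  ddct <- mean(d_treated) - mean(d_control)
  p <- if (length(d_control) >= 2L && length(d_treated) >= 2L &&
           (stats::sd(d_control) > 0 || stats::sd(d_treated) > 0)) {
    stats::t.test(d_treated, d_control)$p.value
  } else {
    NA_real_
  }
  tibble::tibble(
    dct_control = mean(d_control),
    dct_treated = mean(d_treated),
    ddct = ddct,
    fold_change = 2^(-ddct),
    p = p,
    significant = !is.na(p) & p < alpha
  )
}

## replicate-level delta-Ct (target - reference paired by replicate) per
## condition/genotype grouping column
replicate_dct <- function(table, group = "condition") {
  tgt <- table[table$gene == "target", c(group, "replicate", "ct")]
  ref <- table[table$gene == "reference", c(group, "replicate", "ct")]
  names(tgt)[3] <- "ct_target"
  names(ref)[3] <- "ct_reference"
  j <- dplyr::inner_join(tgt, ref, by = c(group, "replicate"))
  if (nrow(j) == 0L) stop("no paired target/reference replicates", call. = FALSE)
  j$dct <- j$ct_target - j$ct_reference
  j
}

#' Relative expression per genotype by the 2^-delta-Ct method
#'
#' @param table tibble with columns `genotype_id`, `gene`
#'   (`target` / `reference`), `replicate`, `ct`.
#' @return tibble: `genotype_id`, `dct` (replicate-averaged), `expression`
#'   = 2^(-dct), `n_reps`.
#' @export
relative_expression_2dct <- function(table) {
  need <- c("genotype_id", "gene", "replicate", "ct")
  stopifnot(all(need %in% names(table)))
  for (g in unique(table$genotype_id)) {
    sub <- table[table$genotype_id == g, ]
    if (!"reference" %in% sub$gene) {
      stop("reference gene missing for genotype '", g, "'", call. = FALSE)
    }
  }
  j <- replicate_dct(table, group = "genotype_id")
  out <- dplyr::summarise(
    dplyr::group_by(j, .data$genotype_id),
    dct = mean(.data$dct), n_reps = dplyr::n(), .groups = "drop"
  )
  dplyr::mutate(out, expression = 2^(-.data$dct), .after = "dct")
}

#' Pearson correlation between expression and a trait
#'
#' @param expr numeric vector of per-genotype expression values (>= 3).
#' @param trait numeric vector of the same length.
#' @return Pearson r.
#' @export
expression_trait_correlation <- function(expr, trait) {
  stopifnot(length(expr) == length(trait))
  if (length(expr) < 3L) stop("need >= 3 paired values", call. = FALSE)
  if (stats::sd(expr) == 0 || stats::sd(trait) == 0) {
    stop("constant vector has no correlation", call. = FALSE)
  }
  stats::cor(expr, trait)
}
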