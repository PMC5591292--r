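#' Pairwise distances from a protein alignment
#'
#' p-distance on pairwise-deleted columns (both sequences non-gap), with
#' optional Poisson correction d = -ln(1 - p). Protein distances only; the
#' default correction is Poisson.
#'
#' @param msa alignment as a named character vector of aligned rows or a
#'   list with `names`/`rows`; at least 3 rows.
#' @param correction `"poisson"` (default) or `"p"`.
#' @return a symmetric distance matrix with labels as dimnames.
#' @export
pairwise_distance <- function(msa, correction = c("poisson", "p")) {
  correction <- match.arg(correction)
  msa <- check_alignment(msa)
  if (length(msa$rows) < 3L) stop("need >= 3 sequences", call. = FALSE)
  m <- do.call(rbind, lapply(msa$rows, chars))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(msa$names, msa$names))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != GAP & m[j, ] != GAP
      if (!any(ok)) {
        stop("no comparable columns between '", msa$names[i], "' and '",
             msa$names[j], "'", call. = FALSE)
      }
      p <- mean(m[i, ok] != m[j, ok])
      if (correction == "poisson") {
        if (p >= 1) {
          stop("saturated pair ('", msa$names[i], "', '", msa$names[j],
               "'): p = 1 has no Poisson distance", call. = FALSE)
        }
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via `ape::nj`), exact on additive
#' matrices. Negative branch-length estimates are clamped to zero with a
#' warning, the common convention.
#'
#' @param d symmetric nonnegative matrix with zero diagonal and labelled
#'   dimnames, or a `dist`.
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d))
  if (nrow(d) < 3L) stop("need >= 3 labels", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is asymmetric", call. = FALSE)
  if (any(d < 0)) stop("distance matrix has negative entries", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero", call. = FALSE)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  tree <- ape::nj(as.dist(d))
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0", call. = FALSE)
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement `n_replicates` times,
#' rebuilds the NJ tree on each replicate, and attaches to each internal
#' edge of the full-data tree the fraction of replicate trees containing
#' the same bipartition. Deterministic given `seed`.
#'
#' @param msa alignment (>= 3 rows).
#' @param n_replicates number of bootstrap replicates (>= 1); the field's
#'   customary default is 1000.
#' @param seed integer seed.
#' @param correction distance correction passed to [pairwise_distance()].
#' @return the NJ tree (`ape::phylo`) with `node.label` holding supports
#'   in \[0, 1\] for internal nodes (NA for the root of the unrooted
#'   representation).
#' @export
bootstrap_support <- function(msa, n_replicates = 1000, seed = 1,
                              correction = "poisson") {
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    stop("n_replicates must be >= 1", call. = FALSE)
  }
  msa <- check_alignment(msa)
  m <- do.call(rbind, lapply(msa$rows, chars))
  n_col <- ncol(m)

  as_msa <- function(mm) list(names = msa$names,
                              rows = apply(mm, 1L, paste, collapse = ""))
  tree <- neighbor_joining(pairwise_distance(as_msa(m), correction))

  variable <- any(apply(m, 2L, function(col) {
    r <- col[col != GAP]
    length(unique(r)) > 1L
  }))
  n_internal <- tree$Nnode
  if (!variable) {
    warning("no variation", call. = FALSE)
    tree$node.label <- rep(0, n_internal)
    return(tree)
  }

  reps <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(k) {
      cols <- sample.int(n_col, n_col, replace = TRUE)
      suppressWarnings(
        tryCatch(
          neighbor_joining(pairwise_distance(as_msa(m[, cols, drop = FALSE]),
                                             correction)),
          error = function(e) NULL
        )
      )
    })
  })
  reps <- Filter(Negate(is.null), reps)
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  tree$node.label <- counts / n_replicates
  tree
}

#' Assign query leaves to named subgroups on a reference-labelled tree
#'
#' For each query leaf, under a midpoint-rooted view of the unrooted tree,
#' the smallest clade containing the query and at least one reference leaf
#' is found. If all reference leaves in that clade share one subgroup, the
#' query is assigned to it; otherwise it is "unclassified". When the mixed
#' subgroups nevertheless share a major group (the Roman-numeral prefix,
#' e.g. IIa and IIb share II), that group is reported in the `group`
#' column with `group_only = TRUE` rather than guessing a subgroup.
#'
#' @param tree an `ape::phylo` with unique leaf labels.
#' @param reference_labels named character vector: leaf label -> subgroup
#'   (e.g. "IIa"); every name must be a leaf of `tree`.
#' @return tibble: `query`, `subgroup`, `group`, `group_only`,
#'   `clade_size` (leaf count of the supporting clade).
#' @export
assign_subgroups <- function(tree, reference_labels) {
  stopifnot(inherits(tree, "phylo"))
  refs <- names(reference_labels)
  missing_ref <- setdiff(refs, tree$tip.label)
  if (length(missing_ref) > 0L) {
    stop("reference label(s) absent from tree: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  queries <- setdiff(tree$tip.label, refs)
  if (length(queries) == 0L) stop("tree has no query leaves", call. = FALSE)

  rooted <- phangorn::midpoint(tree)
  n_tip <- length(rooted$tip.label)
  parent_of <- integer(n_tip + rooted$Nnode)
  parent_of[rooted$edge[, 2L]] <- rooted$edge[, 1L]

  purrr::map_dfr(queries, function(q) {
    ## the clades containing a query are exactly its ancestors: walk up
    ## until the first one that also holds a reference leaf
    node <- match(q, rooted$tip.label)
    cl <- character(0)
    repeat {
      node <- parent_of[node]
      if (node == 0L) break
      cl <- rooted$tip.label[phangorn::Descendants(rooted, node, "tips")[[1L]]]
      if (any(cl %in% refs)) break
    }
    if (!any(cl %in% refs)) {
      return(tibble::tibble(query = q, subgroup = "unclassified",
                            group = NA_character_, group_only = FALSE,
                            clade_size = NA_integer_))
    }
    sg <- unique(unname(reference_labels[intersect(cl, refs)]))
    if (length(sg) == 1L) {
      tibble::tibble(query = q, subgroup = sg,
                     group = sub("[^IVX].*$", "", sg), group_only = FALSE,
                     clade_size = length(cl))
    } else {
      grp <- unique(sub("[^IVX].*$", "", sg))
      tibble::tibble(
        query = q, subgroup = "unclassified",
        group = if (length(grp) == 1L) grp else NA_character_,
        group_only = length(grp) == 1L,
        clade_size = length(cl)
      )
    }
  })
}

#' Write a tree to Newick (supports as internal node labels)
#' @param tree `ape::phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file.
#' @return `ape::phylo`.
#' @export
read_tree_newick <- function(path) {
  ape::read.tree(path)
}
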