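#' Clean a multiple sequence alignment before tree building
#'
#' Applies, in order: (1) removal of insertion column runs -- maximal runs of
#' columns with non-gap fraction < 0.5 -- of run length <= `max_insertion`;
#' (2) cropping of terminal columns until both column coverage (non-gap
#' fraction) >= `min_coverage` and mean pairwise identity >= `min_similarity`;
#' (3) removal of rows left with fewer than `min_len` residues (a row with
#' exactly `min_len` is retained).
#'
#' @param msa character matrix (see [read_msa()]).
#' @param max_insertion maximum insertion run length removed (columns).
#' @param min_coverage minimum terminal column coverage.
#' @param min_similarity minimum terminal column mean pairwise identity.
#' @param min_len minimum residues per retained row.
#' @return the cleaned matrix, with attributes `removed_columns` and
#'   `removed_rows`; errors when nothing survives.
#' @export
clean_alignment <- function(msa, max_insertion = 1000, min_coverage = 0.1,
                            min_similarity = 0.1, min_len = 50) {
  stopifnot(is.matrix(msa), nrow(msa) >= 1)
  orig_cols <- seq_len(ncol(msa))
  orig_rows <- rownames(msa)

  ## (1) insertion runs
  insertion <- colMeans(msa != "-") < 0.5
  drop_col <- rep(FALSE, ncol(msa))
  r <- rle(insertion)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] <= max_insertion) {
      drop_col[starts[k]:ends[k]] <- TRUE
    }
  }
  msa <- msa[, !drop_col, drop = FALSE]
  kept_cols <- orig_cols[!drop_col]
  if (ncol(msa) == 0) stop("alignment cleaning removed all columns")

  ## (2) terminal cropping
  col_ok <- function(j) {
    col <- msa[, j]
    res <- col != "-"
    cov <- mean(res)
    if (sum(res) < 2) return(cov >= min_coverage && min_similarity <= 0)
    counts <- table(col[res])
    n <- sum(res)
    sim <- sum(counts * (counts - 1)) / (n * (n - 1))
    cov >= min_coverage && sim >= min_similarity
  }
  lo <- 1L; hi <- ncol(msa)
  while (lo <= hi && !col_ok(lo)) lo <- lo + 1L
  while (hi >= lo && !col_ok(hi)) hi <- hi - 1L
  if (lo > hi) stop("alignment cleaning removed all columns")
  msa <- msa[, lo:hi, drop = FALSE]
  kept_cols <- kept_cols[lo:hi]

  ## (3) short rows
  res_per_row <- rowSums(msa != "-")
  keep_row <- res_per_row >= min_len
  if (!any(keep_row)) stop("alignment cleaning removed all rows")
  out <- msa[keep_row, , drop = FALSE]
  attr(out, "removed_columns") <- setdiff(orig_cols, kept_cols)
  attr(out, "removed_rows") <- setdiff(orig_rows, rownames(out))
  rs_log("clean_alignment: removed %d columns, %d rows",
         length(attr(out, "removed_columns")), sum(!keep_row))
  out
}

#' Pairwise p-distance matrix of an alignment
#'
#' `d(i, j)` = mismatches / compared sites over the columns where both rows
#' carry residues. Pairs sharing fewer than `min_shared` columns are set to
#' the matrix maximum + 0.1 and flagged (attribute `flagged_pairs`); a pair
#' with zero shared columns additionally warns.
#'
#' @param msa character matrix with unique row names.
#' @param min_shared minimum shared columns for a trusted distance.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(msa, min_shared = 20) {
  stopifnot(is.matrix(msa), nrow(msa) >= 2)
  if (is.null(rownames(msa))) rownames(msa) <- paste0("row", seq_len(nrow(msa)))
  letters_used <- setdiff(unique(as.vector(msa)), "-")
  nongap <- (msa != "-") * 1
  shared <- nongap %*% t(nongap)
  matches <- matrix(0, nrow(msa), nrow(msa))
  for (ch in letters_used) {
    X <- (msa == ch) * 1
    matches <- matches + X %*% t(X)
  }
  mism <- shared - matches
  d <- ifelse(shared > 0, mism / shared, NA)
  diag(d) <- 0
  low <- shared < min_shared
  diag(low) <- FALSE
  if (any(low)) {
    if (any(shared[low] == 0)) {
      warning("row pair(s) with zero shared columns; distance set to max + 0.1")
    }
    mx <- max(d[!low], na.rm = TRUE)
    d[low] <- mx + 0.1
    attr(d, "flagged_pairs") <- which(low & upper.tri(low), arr.ind = TRUE)
  }
  dimnames(d) <- list(rownames(msa), rownames(msa))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via `ape::nj`); negative estimated branch
#' lengths are clamped to 0 with the deficit moved to the sibling branch, so
#' patristic distances through the parent node are preserved.
#'
#' @param d symmetric distance matrix, zero diagonal, n >= 3.
#' @return a `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (any(is.na(d)) || any(!is.finite(d))) stop("NaN/Inf in distance matrix")
  stopifnot(nrow(d) >= 3, isTRUE(all.equal(d, t(d), tolerance = 1e-8)),
            all(abs(diag(d)) < 1e-12))
  tree <- ape::nj(d)
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- tree$edge.length[e]
    parent <- tree$edge[e, 1]
    sib <- which(tree$edge[, 1] == parent)
    sib <- setdiff(sib, e)
    if (length(sib)) {
      tree$edge.length[sib[1]] <- tree$edge.length[sib[1]] + deficit
    }
    tree$edge.length[e] <- 0
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Bootstrap branch supports for a p-distance NJ tree
#'
#' Column-resampled replicates of the alignment are rebuilt with
#' [p_distance_matrix()] + [nj_tree()]; the support of each internal edge of
#' the reference tree is the fraction of replicates containing its
#' bipartition. Supports are stored as `node.label` in `[0, 1]`.
#'
#' @param msa character matrix.
#' @param n_reps number of replicates (>= 1).
#' @param seed RNG seed (supports are deterministic given the seed).
#' @return the reference `phylo` tree with `node.label` supports.
#' @export
bootstrap_supports <- function(msa, n_reps = 100, seed = 1L) {
  stopifnot(n_reps >= 1)
  ref <- nj_tree(p_distance_matrix(msa))
  boots <- with_rng(seed, {
    lapply(seq_len(n_reps), function(i) {
      cols <- sample.int(ncol(msa), ncol(msa), replace = TRUE)
      nj_tree(p_distance_matrix(msa[, cols, drop = FALSE]))
    })
  })
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  ref$node.label <- counts / n_reps
  ref
}

#' Patristic distance between two leaves
#'
#' Sum of branch lengths on the unique path between `leaf_a` and `leaf_b`,
#' in substitutions/site.
#'
#' @param tree a `phylo` tree.
#' @param leaf_a,leaf_b leaf labels.
#' @return non-negative numeric.
#' @export
patristic_distance <- function(tree, leaf_a, leaf_b) {
  missing <- setdiff(c(leaf_a, leaf_b), tree$tip.label)
  if (length(missing)) stop("unknown leaf: ", paste(missing, collapse = ", "))
  if (leaf_a == leaf_b) return(0)
  D <- ape::cophenetic.phylo(tree)
  D[leaf_a, leaf_b]
}

#' Assign query leaves to OTUs by nearest known virus
#'
#' Each query is assigned the OTU of the known leaf at the shortest
#' patristic distance; ties go to the lexicographically smallest known id
#' (logged). The recorded distance feeds the branch-length evidence
#' criterion downstream.
#'
#' @param tree a `phylo` tree containing queries and knowns.
#' @param query_leaves,known_leaves disjoint leaf label sets.
#' @param otu_map named character vector mapping every known leaf to an OTU.
#' @return tibble: `record_id`, `otu`, `nearest_known_id`,
#'   `patristic_distance`.
#' @export
assign_otu <- function(tree, query_leaves, known_leaves, otu_map) {
  if (length(known_leaves) == 0) stop("known_leaves is empty")
  if (length(intersect(query_leaves, known_leaves))) {
    stop("query leaf also listed as known: ",
         paste(intersect(query_leaves, known_leaves), collapse = ", "))
  }
  missing <- setdiff(known_leaves, names(otu_map))
  if (length(missing)) stop("otu_map does not cover: ",
                            paste(missing, collapse = ", "))
  stopifnot(all(c(query_leaves, known_leaves) %in% tree$tip.label))
  D <- ape::cophenetic.phylo(tree)
  known_sorted <- sort(known_leaves)
  purrr::map_dfr(query_leaves, function(q) {
    dq <- D[q, known_sorted]
    best <- min(dq)
    ties <- known_sorted[abs(dq - best) < 1e-12]
    if (length(ties) > 1) {
      rs_log("assign_otu tie for %s among %d knowns, keeping '%s'",
             q, length(ties), ties[1])
    }
    nearest <- ties[1]
    tibble::tibble(record_id = q, otu = unname(otu_map[nearest]),
                   nearest_known_id = nearest, patristic_distance = best)
  })
}

## tip label sets of every internal node of a rooted-format tree
.clade_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  nodes <- (n_tip + 1L):(n_tip + tree$Nnode)
  tips <- phangorn::Descendants(tree, nodes, type = "tips")
  names(tips) <- nodes
  lapply(tips, function(i) tree$tip.label[i])
}

#' Assign query leaves to families via supported monophyletic clades
#'
#' A query receives family `F` iff some clade with branch support
#' `>= min_support` (support exactly at the threshold passes) contains the
#' query and its known leaves are non-empty and all of family `F`; the
#' smallest such clade is used, otherwise the query is unassigned.
#'
#' @param tree a `phylo` tree with numeric `node.label` supports in `[0, 1]`
#'   (`NA`/empty supports never pass).
#' @param query_leaves leaf labels to assign.
#' @param leaf_family_map named character vector: known leaf -> family.
#' @param min_support minimum branch support (default 0.8).
#' @return tibble: `record_id`, `family` (`NA` = unassigned), `clade_size`.
#' @export
assign_family_by_clade <- function(tree, query_leaves, leaf_family_map,
                                   min_support = 0.8) {
  if (is.null(tree$node.label)) stop("tree has no support values")
  if (!ape::is.rooted(tree)) {
    ## clade membership needs a rooting; midpoint unless the caller rooted
    tree <- phangorn::midpoint(tree, node.labels = "support")
  }
  supports <- suppressWarnings(as.numeric(tree$node.label))
  clades <- .clade_tips(tree)
  n_tip <- length(tree$tip.label)
  purrr::map_dfr(query_leaves, function(q) {
    best_family <- NA_character_; best_size <- NA_integer_
    for (k in seq_along(clades)) {
      tips <- clades[[k]]
      if (!q %in% tips) next
      sup <- supports[k]
      if (is.na(sup) || sup < min_support) next
      known <- intersect(tips, names(leaf_family_map))
      if (length(known) == 0) next
      fams <- unique(unname(leaf_family_map[known]))
      if (length(fams) != 1) next
      if (is.na(best_size) || length(tips) < best_size) {
        best_family <- fams; best_size <- length(tips)
      }
    }
    tibble::tibble(record_id = q, family = best_family, clade_size = best_size)
  })
}

#' Normalized Robinson-Foulds congruence between two trees
#'
#' Trees are pruned to their shared leaf set (>= 4 leaves required); the RF
#' distance is divided by `2 * (n - 3)`, so 0 = identical topologies and
#' 1 = maximally different.
#'
#' @param tree_a,tree_b `phylo` trees.
#' @return numeric in `[0, 1]`.
#' @export
tree_congruence <- function(tree_a, tree_b) {
  shared <- intersect(tree_a$tip.label, tree_b$tip.label)
  if (length(shared) < 4) stop("fewer than 4 shared leaves")
  a <- ape::keep.tip(tree_a, shared)
  b <- ape::keep.tip(tree_b, shared)
  a$node.label <- NULL; b$node.label <- NULL
  as.numeric(phangorn::RF.dist(ape::unroot(a), ape::unroot(b),
                               normalize = TRUE, check.labels = TRUE))
}
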