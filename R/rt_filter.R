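## RT purge: split a mixed RdRp/RT reference set via an anchor-driven tree
## bipartition, build paired profiles from the two sub-alignments, and route
## each candidate to the side with the higher domain score.

#' Split a mixed reference alignment into RdRp-like and RT-like sides
#'
#' Finds, over all edges of the tree, the bipartition whose smaller side
#' contains every RdRp anchor and no RT anchor (the smallest clade
#' containing all RdRp anchors); the complement is the RT side, so leaves
#' anchored to neither side follow the complement.
#'
#' @param msa character matrix whose rows include all tree leaves of
#'   interest.
#' @param tree a `phylo` tree over the reference sequences.
#' @param rdrp_anchor_ids,rt_anchor_ids leaf ids anchoring the two sides.
#' @return list with `rdrp_leaves`, `rt_leaves`, `rdrp_msa`, `rt_msa`
#'   (sub-alignments keep the original columns).
#' @export
split_alignment_by_clade <- function(msa, tree, rdrp_anchor_ids,
                                     rt_anchor_ids) {
  stopifnot(length(rdrp_anchor_ids) >= 1, length(rt_anchor_ids) >= 1)
  tips <- tree$tip.label
  missing <- setdiff(c(rdrp_anchor_ids, rt_anchor_ids), tips)
  if (length(missing)) stop("anchor(s) not in tree: ",
                            paste(missing, collapse = ", "))
  missing <- setdiff(c(rdrp_anchor_ids, rt_anchor_ids), rownames(msa))
  if (length(missing)) stop("anchor(s) not in alignment: ",
                            paste(missing, collapse = ", "))
  if (length(intersect(rdrp_anchor_ids, rt_anchor_ids))) {
    stop("anchors overlap between sides")
  }

  ## enumerate the leaf set under each edge (all unrooted bipartitions)
  n_tip <- length(tips)
  sides <- lapply(seq_len(nrow(tree$edge)), function(e) {
    child <- tree$edge[e, 2]
    if (child <= n_tip) tips[child]
    else tips[phangorn::Descendants(tree, child, type = "tips")[[1]]]
  })
  sides <- c(sides, lapply(sides, function(s) setdiff(tips, s)))
  ok <- vapply(sides, function(s) {
    all(rdrp_anchor_ids %in% s) && !any(rt_anchor_ids %in% s)
  }, TRUE)
  if (!any(ok)) {
    mixed <- intersect(rt_anchor_ids,
                       sides[[which.max(vapply(sides, function(s)
                         all(rdrp_anchor_ids %in% s) * -length(s), 0))]])
    stop("anchors not separable: minimal RdRp clade contains RT anchor(s) ",
         paste(if (length(mixed)) mixed else rt_anchor_ids, collapse = ", "))
  }
  sizes <- vapply(sides, length, 0L)
  rdrp_leaves <- sides[[which(ok)[which.min(sizes[ok])]]]
  rt_leaves <- setdiff(tips, rdrp_leaves)
  rs_log("split_alignment_by_clade: %d RdRp-side, %d RT-side leaves",
         length(rdrp_leaves), length(rt_leaves))
  list(rdrp_leaves = rdrp_leaves, rt_leaves = rt_leaves,
       rdrp_msa = msa[intersect(rownames(msa), rdrp_leaves), , drop = FALSE],
       rt_msa = msa[intersect(rownames(msa), rt_leaves), , drop = FALSE])
}

#' Classify one record as RdRp or RT by paired-profile max score
#'
#' `rdrp` iff the RdRp-side Viterbi bit score strictly exceeds the RT-side
#' score; an exact tie goes to `rt` (conservative, logged).
#'
#' @param record one-row tibble with `record_id` and `sequence` (or a plain
#'   sequence string).
#' @param rdrp_profile,rt_profile the paired `ProfileHMM`s.
#' @return one-row tibble: `record_id`, `rdrp_bits`, `rt_bits`, `verdict`.
#' @export
classify_rdrp_vs_rt <- function(record, rdrp_profile, rt_profile) {
  if (is.character(record)) {
    record <- tibble::tibble(record_id = NA_character_, sequence = record)
  }
  a <- viterbi_bits(rdrp_profile, record$sequence, record$record_id)
  b <- viterbi_bits(rt_profile, record$sequence, record$record_id)
  if (a$bits == b$bits) {
    rs_log("classify_rdrp_vs_rt tie for %s at %.3f bits -> rt",
           record$record_id, a$bits)
  }
  tibble::tibble(record_id = record$record_id, rdrp_bits = a$bits,
                 rt_bits = b$bits,
                 verdict = if (a$bits > b$bits) "rdrp" else "rt")
}

#' Apply the RT purge to a set of records
#'
#' @param records tibble with `record_id` and `sequence`.
#' @inheritParams classify_rdrp_vs_rt
#' @return tibble with one row per record (`record_id`, `rdrp_bits`,
#'   `rt_bits`, `verdict`).
#' @export
rt_filter_records <- function(records, rdrp_profile, rt_profile) {
  out <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    classify_rdrp_vs_rt(records[i, ], rdrp_profile, rt_profile)
  })
  rs_log_funnel("rt_filter", nrow(records), sum(out$verdict == "rdrp"))
  out
}
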