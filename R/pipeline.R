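## End-to-end screen: title selection -> dedup -> profile-HMM gate ->
## RT purge via an anchor-split paired-profile comparison -> five-channel
## evidence assembly (internal surrogates) -> two-of-five classification.

#' Build the paired RdRp/RT profiles from a mixed reference alignment
#'
#' Builds an NJ tree over the mixed reference rows, splits it with
#' [split_alignment_by_clade()] using the given anchors, and builds one
#' profile per side.
#'
#' @param mixed_msa character matrix containing both RdRp-like and RT-like
#'   reference rows.
#' @param rdrp_anchor_ids,rt_anchor_ids anchor row/leaf ids.
#' @return list: `rdrp_profile`, `rt_profile`, `split`.
#' @export
build_paired_profiles <- function(mixed_msa, rdrp_anchor_ids, rt_anchor_ids) {
  tree <- nj_tree(p_distance_matrix(mixed_msa))
  split <- split_alignment_by_clade(mixed_msa, tree, rdrp_anchor_ids,
                                    rt_anchor_ids)
  list(rdrp_profile = build_profile(split$rdrp_msa, "RDRP_side"),
       rt_profile = build_profile(split$rt_msa, "RT_side"),
       split = split)
}

#' Run the full RdRp screen on a corpus
#'
#' Stages: (1) unknown-protein title selection; (2) duplicate/known-id
#' removal; (3) domain-score gate at `gate_bits` (inclusive) against the
#' RdRp profile; (4) RT purge by paired-profile max score, the pair coming
#' from an anchor-driven clade split of the built-in mixed reference set;
#' (5) evidence assembly with internal surrogates -- palmprint detection,
#' local-alignment bits against the known panel (RdRp and RT sides),
#' profile-anchored NJ placement distance to the nearest known virus, and
#' the domain score; (6) the two-of-five rule with RT exclusion.
#'
#' @param records corpus tibble (see [generate_corpus()] / [read_corpus()]).
#' @param gate_bits domain-score gate (default 25).
#' @param thresholds evidence thresholds, see [default_thresholds()].
#' @param panel known-reference panel (default
#'   [generate_reference_panel()]).
#' @param known_rdrp_ids ids excluded at the dedup stage.
#' @return list: `results` (one row per input record with `verdict` in
#'   rdrp / rt_like / insufficient / not_gated / not_selected), `hits`,
#'   `rt_filter`, `bundles`, `calls`, `placements`, `funnel`.
#' @export
run_screen <- function(records, gate_bits = 25,
                       thresholds = default_thresholds(), panel = NULL,
                       known_rdrp_ids = character()) {
  if (is.null(panel)) panel <- generate_reference_panel()
  funnel <- list(input = nrow(records))

  sel <- select_uncharacterized(records)
  funnel$selected <- nrow(sel)
  ded <- dedup_records(sel, known_rdrp_ids)
  funnel$deduplicated <- nrow(ded)

  prof <- builtin_profiles()
  hits <- scan_profiles(ded, list(prof$mixed), gate_bits = gate_bits)
  funnel$gated <- nrow(hits)
  gated <- ded[match(hits$record_id, ded$record_id), ]

  msas <- builtin_seed_msas()
  mixed <- rbind(msas$rdrp, msas$rt)
  paired <- build_paired_profiles(mixed,
                                  rdrp_anchor_ids = rownames(msas$rdrp),
                                  rt_anchor_ids = rownames(msas$rt))
  rtres <- rt_filter_records(gated, paired$rdrp_profile, paired$rt_profile)
  surv <- gated[rtres$verdict == "rdrp", , drop = FALSE]
  funnel$after_rt_purge <- nrow(surv)

  calls <- NULL; bundles <- NULL; placements <- NULL
  if (nrow(surv) > 0) {
    palm <- vapply(surv$sequence, function(s) detect_palmprint(s)$core, "")
    rdrp_panel <- panel[panel$class == "rdrp", ]
    rt_panel <- panel[panel$class == "rt", ]
    blast_rdrp <- lapply(surv$sequence, best_panel_hit, panel = rdrp_panel)
    blast_rt <- lapply(surv$sequence, best_panel_hit, panel = rt_panel)

    ## profile-anchored placement among the known RdRp references
    aln <- profile_align(paired$rdrp_profile,
                         dplyr::bind_rows(
                           surv[, c("record_id", "sequence")],
                           rdrp_panel[, c("record_id", "sequence")]))
    placements <- tryCatch({
      tr <- nj_tree(p_distance_matrix(aln))
      assign_otu(tr, query_leaves = surv$record_id,
                 known_leaves = rdrp_panel$record_id,
                 otu_map = setNames(rdrp_panel$otu, rdrp_panel$record_id))
    }, error = function(e) {
      rs_log("placement skipped: %s", conditionMessage(e))
      NULL
    })

    bundles <- tibble::tibble(
      record_id = surv$record_id,
      palmprint = unname(palm),
      blast_rdrp_bits = vapply(blast_rdrp, `[[`, 0, "bits"),
      blast_subject_id = vapply(blast_rdrp, `[[`, "", "subject_id"),
      blast_rt_bits = vapply(blast_rt, `[[`, 0, "bits"),
      tree_distance = if (is.null(placements)) NA_real_ else
        placements$patristic_distance[match(surv$record_id,
                                            placements$record_id)],
      hmmer_bits = rtres$rdrp_bits[rtres$verdict == "rdrp"]
    )
    calls <- integrate_evidence(bundles, thresholds)
    funnel$rdrp <- sum(calls$verdict == "rdrp")
  } else {
    funnel$rdrp <- 0L
  }

  verdict <- rep("not_selected", nrow(records))
  names(verdict) <- records$record_id
  verdict[ded$record_id] <- "not_gated"
  verdict[rtres$record_id[rtres$verdict == "rt"]] <- "rt_like"
  if (!is.null(calls)) verdict[calls$record_id] <- calls$verdict
  rs_log("run_screen funnel: %s",
         paste(sprintf("%s=%d", names(funnel), unlist(funnel)),
               collapse = ", "))
  list(results = tibble::tibble(record_id = records$record_id,
                                verdict = unname(verdict)),
       hits = hits, rt_filter = rtres, bundles = bundles, calls = calls,
       placements = placements, funnel = funnel, paired = paired)
}
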