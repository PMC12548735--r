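## Near-miss band selection, term enrichment, negative-control (NC) and
## near-miss (NM) control-set construction, mislabel flagging and the
## records-per-species proxy.

#' Select near-miss records from domain scores
#'
#' The near-miss band is `[lower, upper)` bits -- half-open so it is
#' disjoint from the inclusive `>= 25` candidate gate (a score of exactly
#' 10 is a near-miss, exactly 25 is a candidate).
#'
#' @param scores tibble with `record_id` and `bits`.
#' @param lower,upper band bounds (default 10 and 25).
#' @return the subset of `scores` in the band.
#' @export
select_near_miss <- function(scores, lower = 10, upper = 25) {
  out <- scores[scores$bits >= lower & scores$bits < upper, , drop = FALSE]
  rs_log_funnel(sprintf("select_near_miss [%g, %g)", lower, upper),
                nrow(scores), nrow(out))
  out
}

#' Term enrichment between a test and a control set
#'
#' Per-term `log2[(count_test / total_test) / (count_ctrl / total_ctrl)]`,
#' ranked descending. Terms absent from both sets are omitted. With
#' `zero_policy = "haldane"`, 0.5 is added to both counts of a term when
#' either count is zero (keeping the fold change finite); with `"omit"`,
#' such terms are dropped. A two-sided Fisher exact p-value is reported for
#' reference but never used for ranking; ties are broken by larger
#' `count_test`, then term string.
#'
#' @param test_counts,ctrl_counts named integer vectors (term -> count).
#' @param total_test,total_ctrl set sizes (> 0).
#' @param zero_policy `"haldane"` (default) or `"omit"`.
#' @param with_p compute Fisher p-values (slower on many terms).
#' @return tibble: `term`, `count_test`, `total_test`, `count_ctrl`,
#'   `total_ctrl`, `log2_fold_change`, `p_value`, ranked descending.
#' @export
term_enrichment <- function(test_counts, total_test, ctrl_counts, total_ctrl,
                            zero_policy = c("haldane", "omit"),
                            with_p = TRUE) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(total_test > 0, total_ctrl > 0,
            all(test_counts >= 0), all(ctrl_counts >= 0),
            all(test_counts <= total_test), all(ctrl_counts <= total_ctrl))
  terms <- union(names(test_counts), names(ctrl_counts))
  ct <- setNames(rep(0, length(terms)), terms)
  cc <- ct
  ct[names(test_counts)] <- test_counts
  cc[names(ctrl_counts)] <- ctrl_counts
  present <- ct > 0 | cc > 0
  ct <- ct[present]; cc <- cc[present]; terms <- terms[present]
  if (!length(terms)) {
    return(tibble::tibble(term = character(), count_test = numeric(),
                          total_test = numeric(), count_ctrl = numeric(),
                          total_ctrl = numeric(), log2_fold_change = numeric(),
                          p_value = numeric()))
  }
  at <- ct; ac <- cc
  zero <- ct == 0 | cc == 0
  if (zero_policy == "haldane") {
    at[zero] <- at[zero] + 0.5
    ac[zero] <- ac[zero] + 0.5
  } else {
    keep <- !zero
    at <- at[keep]; ac <- ac[keep]; ct <- ct[keep]; cc <- cc[keep]
    terms <- terms[keep]
  }
  lfc <- log2((at / total_test) / (ac / total_ctrl))
  pv <- rep(NA_real_, length(terms))
  if (with_p) {
    pv <- vapply(seq_along(terms), function(i) {
      stats::fisher.test(matrix(c(ct[i], total_test - ct[i],
                                  cc[i], total_ctrl - cc[i]),
                                nrow = 2))$p.value
    }, 0)
  }
  out <- tibble::tibble(term = terms, count_test = unname(ct),
                        total_test = total_test, count_ctrl = unname(cc),
                        total_ctrl = total_ctrl,
                        log2_fold_change = unname(lfc), p_value = pv)
  out[order(-out$log2_fold_change, -out$count_test, out$term), ]
}

#' Build the NC and NM negative-control protein sets
#'
#' Base filter (all required): at least five significant BLASTP hits
#' (bits above 50, identity above 40%, alignment length above 100, all
#' strict) against
#' characterized non-RNA-viral proteins; zero hits meeting those criteria
#' against characterized RNA-viral proteins; at least one CDD annotation,
#' none exclusive to RNA viruses; and no palmprint hit against RdRp.
#' NC additionally requires no domain score >= 10; NM requires a domain
#' score in `[10, 25)`. Sets are truncated to `set_size` by record-id sort
#' (deterministic, input-order independent) and are disjoint by
#' construction.
#'
#' @param annotations list with elements `records` (character vector of
#'   candidate ids), `blast` (tibble `record_id`, `subject_id`, `bits`,
#'   `pct_identity`, `aln_length`, `subject_class` in
#'   rna_viral/non_rna_viral/uncharacterized), `cdd` (tibble `record_id`,
#'   `term_id`, `rna_virus_exclusive`), `palmprint` (tibble `record_id`,
#'   `core`), `hmmer` (tibble `record_id`, `bits`; absent ids = no score).
#' @param set_size maximum ids per set.
#' @return list with sorted character vectors `nc` and `nm`.
#' @export
build_control_sets <- function(annotations, set_size = 20000) {
  ids <- sort(unique(annotations$records))
  blast <- annotations$blast
  cdd <- annotations$cdd
  palm <- annotations$palmprint
  hmmer <- annotations$hmmer
  stopifnot(!is.null(blast), !is.null(cdd))

  qual <- blast[blast$bits > 50 & blast$pct_identity > 40 &
                  blast$aln_length > 100 &
                  blast$subject_class != "uncharacterized", , drop = FALSE]
  n_nonviral <- table(factor(qual$record_id[qual$subject_class == "non_rna_viral"],
                             levels = ids))
  n_viral <- table(factor(qual$record_id[qual$subject_class == "rna_viral"],
                          levels = ids))
  has_cdd <- table(factor(cdd$record_id, levels = ids)) >= 1
  bad_cdd <- table(factor(cdd$record_id[cdd$rna_virus_exclusive], levels = ids)) >= 1
  palm_rdrp <- if (is.null(palm)) rep(FALSE, length(ids)) else {
    ids %in% palm$record_id[palm$core == "rdrp_core"]
  }
  hmm_bits <- if (is.null(hmmer)) rep(NA_real_, length(ids)) else {
    hmmer$bits[match(ids, hmmer$record_id)]
  }

  base <- as.vector(n_nonviral) >= 5 & as.vector(n_viral) == 0 &
    as.vector(has_cdd) & !as.vector(bad_cdd) & !palm_rdrp
  nc <- ids[base & (is.na(hmm_bits) | hmm_bits < 10)]
  nm <- ids[base & !is.na(hmm_bits) & hmm_bits >= 10 & hmm_bits < 25]
  for (nm_set in list(c("NC", length(nc)), c("NM", length(nm)))) {
    if (as.integer(nm_set[2]) < set_size) {
      warning(nm_set[1], " set has only ", nm_set[2],
              " eligible records (requested ", set_size, ")")
    }
  }
  list(nc = head(nc, set_size), nm = head(nm, set_size))
}

#' Flag bacteria/archaea-labelled records matching known RNA viruses
#'
#' Records labelled bacterial or archaeal whose best match against an
#' ICTV-classified RNA virus RdRp has identity > 85% and bit score > 400
#' are flagged as likely mislabelled or contaminant-derived.
#'
#' @param records corpus tibble with `record_id` and `taxon_label`.
#' @param best_viral_match tibble: `record_id`, `virus_id`, `pct_identity`,
#'   `bits` (best ICTV-virus match per record).
#' @return tibble: `record_id`, `flagged`, `matched_virus`.
#' @export
flag_mislabelled <- function(records, best_viral_match) {
  m <- best_viral_match[match(records$record_id, best_viral_match$record_id), ]
  flagged <- records$taxon_label %in% c("bacteria", "archaea") &
    !is.na(m$pct_identity) & m$pct_identity > 85 &
    !is.na(m$bits) & m$bits > 400
  tibble::tibble(record_id = records$record_id, flagged = flagged,
                 matched_virus = ifelse(flagged, m$virus_id, NA_character_))
}

#' Median protein-records-per-species, all vs flagged viruses
#'
#' The how-widely-studied proxy: the median record count over all species
#' compared with the median over the flagged subset.
#'
#' @param species_record_counts named numeric vector (species -> count >= 0).
#' @param flagged_species subset of `names(species_record_counts)`.
#' @return list: `median_all`, `median_flagged` (`NA` when no species is
#'   flagged).
#' @export
records_per_species_proxy <- function(species_record_counts, flagged_species) {
  stopifnot(all(species_record_counts >= 0),
            all(flagged_species %in% names(species_record_counts)))
  list(median_all = median(species_record_counts),
       median_flagged = if (length(flagged_species)) {
         median(species_record_counts[flagged_species])
       } else NA_real_)
}
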