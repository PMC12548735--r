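## Five-channel evidence model and the two-of-five classification rule.
## Channels: FoldSeek structure bits, palmprint core, BLAST-type bits
## against known RdRps, patristic distance to the nearest known virus, and
## the profile-HMM domain score. An absent channel can never satisfy a
## criterion (and is never counted as a failure).

#' Default evidence thresholds
#'
#' The printed screening thresholds: FoldSeek > 100 bits, BLAST > 50 bits,
#' tree distance < 1.5 substitutions/site, HMMER domain score > 50 bits
#' (all strict), plus the RT-exclusion BLAST floor (>= 50, a symmetric
#' default for the unquantified "high-scoring match against RT").
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(foldseek = 100, blast = 50, tree = 1.5, hmmer = 50, rt_blast_min = 50)
}

.BUNDLE_COLS <- c("record_id", "foldseek_bits", "palmprint", "blast_rdrp_bits",
                  "blast_subject_id", "blast_rt_bits", "tree_distance",
                  "hmmer_bits")

## normalize a bundle (list or tibble, one row per record) to full width
as_evidence_bundle <- function(bundle) {
  if (!is.data.frame(bundle)) bundle <- tibble::as_tibble(bundle)
  if (!"record_id" %in% names(bundle)) stop("malformed bundle: no record_id")
  for (col in .BUNDLE_COLS) {
    if (!col %in% names(bundle)) {
      bundle[[col]] <- if (col == "palmprint") "none"
      else if (col == "blast_subject_id") NA_character_ else NA_real_
    }
  }
  bundle$palmprint[is.na(bundle$palmprint)] <- "none"
  if (!all(bundle$palmprint %in% c("rdrp_core", "rt_core", "none"))) {
    stop("malformed bundle: bad palmprint value")
  }
  channels <- c("foldseek_bits", "blast_rdrp_bits", "blast_rt_bits",
                "tree_distance", "hmmer_bits")
  present <- rowSums(!is.na(bundle[channels])) + (bundle$palmprint != "none")
  if (any(present == 0)) {
    stop("malformed bundle: no evidence channel present for ",
         bundle$record_id[present == 0][1])
  }
  bundle[, .BUNDLE_COLS]
}

#' Integrate the five evidence channels into an RdRp call
#'
#' Criteria (all strict inequalities, exactly as printed): (i) FoldSeek
#' bits above 100; (ii) palmprint core = `rdrp_core`; (iii) BLAST bits
#' above 50 against a known RdRp; (iv) tree distance below 1.5
#' substitutions/site; (v) domain score above 50 bits. A record is `rdrp`
#' when two or more criteria hold,
#' unless excluded as RT: palmprint `rt_core`, or an RT BLAST score at
#' least `rt_blast_min` that exceeds the RdRp BLAST score (0 when absent).
#'
#' @param bundle evidence bundle(s): list or tibble with `record_id` and any
#'   of `foldseek_bits`, `palmprint`, `blast_rdrp_bits`, `blast_rt_bits`,
#'   `tree_distance`, `hmmer_bits`.
#' @param thresholds see [default_thresholds()].
#' @return tibble with the five criterion booleans, `n_met`,
#'   `excluded_as_rt` and `verdict` (`rdrp` / `rt_like` / `insufficient`).
#' @export
integrate_evidence <- function(bundle, thresholds = default_thresholds()) {
  b <- as_evidence_bundle(bundle)
  crit_foldseek <- !is.na(b$foldseek_bits) & b$foldseek_bits > thresholds$foldseek
  crit_palmprint <- b$palmprint == "rdrp_core"
  crit_blast <- !is.na(b$blast_rdrp_bits) & b$blast_rdrp_bits > thresholds$blast
  crit_tree <- !is.na(b$tree_distance) & b$tree_distance < thresholds$tree
  crit_hmmer <- !is.na(b$hmmer_bits) & b$hmmer_bits > thresholds$hmmer
  n_met <- crit_foldseek + crit_palmprint + crit_blast + crit_tree + crit_hmmer
  rdrp_ref <- ifelse(is.na(b$blast_rdrp_bits), 0, b$blast_rdrp_bits)
  excluded <- b$palmprint == "rt_core" |
    (!is.na(b$blast_rt_bits) & b$blast_rt_bits >= thresholds$rt_blast_min &
       b$blast_rt_bits > rdrp_ref)
  tibble::tibble(
    record_id = b$record_id,
    crit_foldseek = crit_foldseek, crit_palmprint = crit_palmprint,
    crit_blast = crit_blast, crit_tree = crit_tree, crit_hmmer = crit_hmmer,
    n_met = as.integer(n_met), excluded_as_rt = excluded,
    verdict = dplyr::case_when(excluded ~ "rt_like",
                               n_met >= 2 ~ "rdrp",
                               TRUE ~ "insufficient")
  )
}

#' Remove duplicate and already-known records
#'
#' Exact-sequence duplicate groups keep one representative, preferring a
#' non-RefSeq accession (RefSeq recognized by an underscore in the accession
#' prefix, e.g. `XP_`, `NP_`); records whose id is in `known_rdrp_ids` are
#' removed.
#'
#' @param records corpus tibble with `record_id` and `sequence`.
#' @param known_rdrp_ids ids of proteins already known to be RdRp.
#' @return the deduplicated subset, original order preserved.
#' @export
dedup_records <- function(records, known_rdrp_ids = character()) {
  n_in <- nrow(records)
  is_refseq <- grepl("_", sub("\\..*$", "", records$record_id))
  ord <- order(is_refseq, records$record_id)  # preferred representative first
  keep_ids <- records$record_id[ord][!duplicated(records$sequence[ord])]
  out <- records[records$record_id %in% keep_ids &
                   !records$record_id %in% known_rdrp_ids, , drop = FALSE]
  rs_log_funnel("dedup_records", n_in, nrow(out))
  out
}

.check_table <- function(tbl, what, universe) {
  if (is.null(tbl)) return(invisible(NULL))
  if (anyDuplicated(tbl$record_id)) {
    stop("conflicting duplicate ", what, " rows for record ",
         tbl$record_id[duplicated(tbl$record_id)][1])
  }
  unknown <- setdiff(tbl$record_id, universe)
  if (length(unknown)) {
    stop("unknown record_id in ", what, " table: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  invisible(NULL)
}

#' Assemble evidence bundles from pre-parsed evidence tables
#'
#' Adapter that lets real FoldSeek / PalmScan / BLAST / placement outputs
#' (as TSV-derived tibbles keyed by `record_id`) replace the internal
#' surrogates. Missing tables leave the channel absent.
#'
#' @param records corpus tibble (defines the id universe).
#' @param hits domain-score hits, columns `record_id`, `bits`.
#' @param foldseek optional tibble `record_id`, `bits`.
#' @param palm optional tibble `record_id`, `core`.
#' @param blast optional tibble `record_id`, `rdrp_bits`, `rt_bits`,
#'   `subject_id`.
#' @param placements optional tibble `record_id`, `patristic_distance`.
#' @return evidence bundle tibble (one row per record in `hits`).
#' @export
evidence_from_tables <- function(records, hits, foldseek = NULL, palm = NULL,
                                 blast = NULL, placements = NULL) {
  universe <- records$record_id
  .check_table(hits, "hits", universe)
  .check_table(foldseek, "foldseek", universe)
  .check_table(palm, "palmprint", universe)
  .check_table(blast, "blast", universe)
  .check_table(placements, "placements", universe)
  out <- tibble::tibble(record_id = hits$record_id, hmmer_bits = hits$bits)
  pick <- function(tbl, col, default = NA_real_) {
    if (is.null(tbl)) return(rep(default, nrow(out)))
    v <- tbl[[col]][match(out$record_id, tbl$record_id)]
    if (is.character(default)) v[is.na(v)] <- default
    v
  }
  out$foldseek_bits <- pick(foldseek, "bits")
  out$palmprint <- pick(palm, "core", "none")
  out$blast_rdrp_bits <- pick(blast, "rdrp_bits")
  out$blast_rt_bits <- pick(blast, "rt_bits")
  out$blast_subject_id <- pick(blast, "subject_id", NA_character_)
  out$tree_distance <- pick(placements, "patristic_distance")
  as_evidence_bundle(out)
}
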