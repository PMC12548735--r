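## EVE-vs-exogenous signatures: source molecule type, contig length scale,
## ORF length and degradation (premature stops, frameshifts), and the
## shared-insertion-site test on whole-genome alignment blocks.

.revcomp <- function(nt) {
  paste0(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", nt), "")[[1]]),
         collapse = "")
}

.frame_translation <- function(nt, offset) {
  translate_nt(substr(nt, offset + 1L, nchar(nt)))
}

#' Longest ATG-initiated open reading frame
#'
#' Scans all six frames (three if `both_strands = FALSE`) for the longest
#' ORF that starts at ATG and runs to the next stop codon (or the end of
#' the frame when no stop follows). The interval is 0-based half-open in
#' nucleotides on the reported strand and covers start through stop codon.
#'
#' @param nt nucleotide sequence (>= 3 nt).
#' @param both_strands scan the reverse complement too.
#' @return list: `aa_length` (0 when no ATG-initiated ORF exists),
#'   `interval` (`NULL` when absent), `strand` (`"+"`/`"-"`), `frame` (0-2).
#' @export
longest_orf <- function(nt, both_strands = TRUE) {
  nt <- toupper(nt)
  if (nchar(nt) < 3) stop("sequence shorter than 3 nt")
  if (grepl("[^ACGT]", nt)) stop("non-ACGT character in nucleotide sequence")
  best <- list(aa_length = 0L, interval = NULL, strand = "+", frame = 0L)
  strands <- if (both_strands) c("+", "-") else "+"
  for (strand in strands) {
    s <- if (strand == "+") nt else .revcomp(nt)
    for (off in 0:2) {
      aa <- strsplit(.frame_translation(s, off), "")[[1]]
      if (!length(aa)) next
      bounds <- c(0L, which(aa == "*"), length(aa) + 1L)
      for (k in seq_len(length(bounds) - 1L)) {
        lo <- bounds[k] + 1L; hi <- bounds[k + 1L]  # hi = stop or past-end
        if (lo >= hi) next
        seg <- aa[lo:(hi - 1L)]
        m <- match("M", seg)
        if (is.na(m)) next
        start_aa <- lo + m - 1L
        len <- hi - start_aa  # codons from ATG up to (excl.) stop/end
        if (len > best$aa_length) {
          has_stop <- hi <= length(aa)
          nt_start <- off + 3L * (start_aa - 1L)
          nt_end <- off + 3L * (hi - 1L) + (if (has_stop) 3L else 0L)
          best <- list(aa_length = len, interval = c(nt_start, nt_end),
                       strand = strand, frame = off)
        }
      }
    }
  }
  best
}

.internal_stops <- function(aa) {
  stops <- sum(aa == "*")
  if (length(aa) && aa[length(aa)] == "*") stops <- stops - 1L
  stops
}

#' Stop-codon and frameshift degradation metrics for a nucleotide region
#'
#' The best reading frame is the forward frame minimizing internal stop
#' codons; `stops_per_100_codons` is computed on that frame. With a
#' reference protein, the region is cut into disjoint windows, each window
#' is assigned to the frame whose translation aligns best to the reference
#' (ungapped local alignment, at least `min_bits`), and a frameshift is
#' called when two or more frames own windows. Without a reference, sliding
#' windows are examined: the flag is raised when some window's stop count
#' in the global best frame is >= 2 and exceeds three times the window
#' minimum over frames.
#'
#' @param nt nucleotide region (>= 30 nt).
#' @param reference optional intact reference protein sequence.
#' @param window,step sliding window size and step (nt).
#' @param min_bits minimum local-alignment bits for a frame to count as
#'   matching the reference.
#' @return list: `stops_per_100_codons`, `frameshift_flag`, `best_frame`.
#' @export
degradation_metrics <- function(nt, reference = NULL, window = 150L,
                                step = 75L, min_bits = 25) {
  nt <- toupper(nt)
  stopifnot(nchar(nt) >= 30)
  frames <- lapply(0:2, function(off) strsplit(.frame_translation(nt, off), "")[[1]])
  stops <- vapply(frames, .internal_stops, 0L)
  best <- which.min(stops) - 1L
  n_codons <- length(frames[[best + 1L]])
  rate <- stops[best + 1L] / n_codons * 100

  flag <- FALSE
  if (!is.null(reference)) {
    ## assign disjoint windows to the frame whose translation aligns best
    ## to the reference; two or more owning frames = frameshift. Gapped
    ## whole-length alignments are useless here: they bridge straight
    ## across the frameshift junction.
    ref <- Biostrings::AAString(reference)
    win <- 60L
    starts <- seq(1L, max(1L, nchar(nt) - win + 1L), by = win)
    owner <- integer(0)
    for (s in starts) {
      chunk <- substr(nt, s, min(nchar(nt), s + win - 1L))
      if (nchar(chunk) < 30) next
      bits <- vapply(0:2, function(off) {
        tr <- gsub("*", "X", .frame_translation(chunk, off), fixed = TRUE)
        if (nchar(tr) < 10) return(-Inf)
        sc <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(tr), ref, type = "local",
          substitutionMatrix = "BLOSUM62", gapOpening = 1e5,
          gapExtension = 1, scoreOnly = TRUE)
        (0.267 * max(0, sc) - log(0.041)) / log(2)
      }, 0)
      if (max(bits) >= min_bits) owner <- c(owner, which.max(bits))
    }
    flag <- length(unique(owner)) >= 2
  } else {
    starts <- seq(1L, max(1L, nchar(nt) - window + 1L), by = step)
    for (s in starts) {
      win <- substr(nt, s, min(nchar(nt), s + window - 1L))
      if (nchar(win) < 30) next
      wstops <- vapply(0:2, function(off) {
        .internal_stops(strsplit(.frame_translation(win, off), "")[[1]])
      }, 0L)
      if (wstops[best + 1L] >= 2 && wstops[best + 1L] > 3 * min(wstops)) {
        flag <- TRUE
      }
    }
  }
  list(stops_per_100_codons = rate, frameshift_flag = flag, best_frame = best)
}

#' Cohort-level EVE signatures
#'
#' Per-group record counts and mean contig / protein lengths, with fold
#' changes against a reference group. With the default grouping, records
#' are pooled into `dna_source` (`genomic_dna`) and `rna_source`
#' (`mrna` + `assembled_rna`) cohorts, the comparison behind the
#' chromosome-scale-contig and shortened-ORF endogeneity arguments.
#'
#' @param records corpus tibble.
#' @param grouping `"molecule_type"` (pooled as above) or the name of any
#'   column of `records`.
#' @param reference_group group used as fold-change denominator (default
#'   `rna_source`); folds are absent when it is empty.
#' @return tibble: `group`, `n`, `n_contig_absent`, `mean_contig_length_nt`,
#'   `mean_protein_length_aa`, `contig_fold_vs_reference`,
#'   `protein_fold_vs_reference`.
#' @export
cohort_signatures <- function(records, grouping = "molecule_type",
                              reference_group = "rna_source") {
  if (grouping == "molecule_type") {
    grp <- dplyr::case_when(
      records$molecule_type == "genomic_dna" ~ "dna_source",
      records$molecule_type %in% c("mrna", "assembled_rna") ~ "rna_source",
      TRUE ~ "unknown_source")
  } else {
    grp <- as.character(records[[grouping]])
  }
  df <- tibble::tibble(group = grp,
                       contig = records$contig_length_nt,
                       plen = nchar(records$sequence))
  out <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_contig_absent = sum(is.na(.data$contig)),
      mean_contig_length_nt = mean(.data$contig, na.rm = TRUE),
      mean_protein_length_aa = mean(.data$plen),
      .groups = "drop")
  ref <- out[out$group == reference_group, ]
  if (nrow(ref) == 1 && ref$n >= 1) {
    out$contig_fold_vs_reference <-
      out$mean_contig_length_nt / ref$mean_contig_length_nt
    out$protein_fold_vs_reference <-
      out$mean_protein_length_aa / ref$mean_protein_length_aa
  } else {
    out$contig_fold_vs_reference <- NA_real_
    out$protein_fold_vs_reference <- NA_real_
  }
  out
}

#' Construct an EVE locus descriptor
#' @param genome,chrom identifiers; `start`,`end` 0-based half-open nt.
#' @return a named list.
#' @export
eve_locus <- function(genome, chrom, start, end) {
  stopifnot(end > start, start >= 0)
  list(genome = genome, chrom = chrom, start = start, end = end)
}

## does `block` (one row, oriented so side "a" matches locus) contain locus
## with the required flank on both sides?
.contains_with_flank <- function(start, end, locus, flank) {
  start + flank <= locus$start && end - flank >= locus$end
}

#' Shared-insertion-site test for two EVE loci
#'
#' Two loci share an insertion site when a single whole-genome alignment
#' block pair longer than `min_block_nt` (strict, on both genomes) contains
#' both loci with non-EVE flanking sequence of at least `min_flank_nt` on
#' each side in each genome. When both loci sit in long well-aligned blocks
#' but never the same pair, the sites are `not_shared`; anything else
#' (fragmented assemblies, sub-threshold blocks) is `undetermined`.
#'
#' @param locus_a,locus_b [eve_locus()] descriptors in two genomes.
#' @param alignment_blocks tibble with columns `genome_a`, `chrom_a`,
#'   `start_a`, `end_a`, `genome_b`, `chrom_b`, `start_b`, `end_b`,
#'   `pct_identity` (0-based half-open intervals).
#' @param min_block_nt minimum block length, strict (8000 exactly fails).
#' @param min_flank_nt minimum non-EVE flank inside the block on each side.
#' @return `"shared"`, `"not_shared"` or `"undetermined"`.
#' @export
shared_insertion_site <- function(locus_a, locus_b, alignment_blocks,
                                  min_block_nt = 8000, min_flank_nt = 500) {
  blk <- alignment_blocks
  stopifnot(all(c("genome_a", "chrom_a", "start_a", "end_a", "genome_b",
                  "chrom_b", "start_b", "end_b") %in% names(blk)))
  if (!is.null(blk$pct_identity)) {
    stopifnot(all(blk$pct_identity >= 0 & blk$pct_identity <= 100))
  }
  ## orient every block so that side "a" refers to locus_a's genome
  fwd <- blk[blk$genome_a == locus_a$genome & blk$genome_b == locus_b$genome, ]
  rev <- blk[blk$genome_b == locus_a$genome & blk$genome_a == locus_b$genome, ]
  if (nrow(rev)) {
    rev <- tibble::tibble(genome_a = rev$genome_b, chrom_a = rev$chrom_b,
                          start_a = rev$start_b, end_a = rev$end_b,
                          genome_b = rev$genome_a, chrom_b = rev$chrom_a,
                          start_b = rev$start_a, end_b = rev$end_a)
  }
  blk <- dplyr::bind_rows(fwd[, names(rev) %||% names(fwd)], rev)
  if (nrow(blk) == 0) {
    warning("no alignment blocks between the two genomes; undetermined")
    return("undetermined")
  }
  big <- (blk$end_a - blk$start_a) > min_block_nt &
    (blk$end_b - blk$start_b) > min_block_nt
  on_a <- blk$chrom_a == locus_a$chrom
  on_b <- blk$chrom_b == locus_b$chrom
  holds_a <- on_a & mapply(.contains_with_flank, blk$start_a, blk$end_a,
                           MoreArgs = list(locus = locus_a, flank = min_flank_nt))
  holds_b <- on_b & mapply(.contains_with_flank, blk$start_b, blk$end_b,
                           MoreArgs = list(locus = locus_b, flank = min_flank_nt))
  if (any(big & holds_a & holds_b)) return("shared")
  covered_a <- any(big & holds_a)
  covered_b <- any(big & holds_b)
  if (covered_a && covered_b) return("not_shared")
  "undetermined"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
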