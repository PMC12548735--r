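## Palmprint surrogate: a three-block ordered motif detector standing in for
## PalmScan. The conserved palm core is modelled as three short blocks
## (A/B/C-style); the B block carries the catalytic triad, GDD in RNA viral
## RdRp versus the YxDD variant typical of reverse transcriptase.

PALM_A <- "DYSKWD"
PALM_B_RDRP <- "MSGDDS"
PALM_B_RT <- "MYVDDL"
PALM_C <- "FLKRHF"
PALM_GAP_RANGE <- c(5L, 150L)  # residues allowed between block end and next start

## positions (1-based) where `motif` matches `chars` with <= max_mismatch
## substitutions; returns a data.frame of pos and mismatch count
.motif_hits <- function(chars, motif, max_mismatch) {
  m <- strsplit(motif, "")[[1]]
  k <- length(m)
  n <- length(chars)
  if (n < k) return(data.frame(pos = integer(), mm = integer()))
  mism <- integer(n - k + 1)
  for (o in seq_len(k)) {
    mism <- mism + (chars[seq_len(n - k + 1) + o - 1L] != m[o])
  }
  keep <- which(mism <= max_mismatch)
  data.frame(pos = keep, mm = mism[keep])
}

#' Detect an RdRp- or RT-like palm core in a protein sequence
#'
#' Searches for the three ordered palm blocks (A, B, C) with at most
#' `max_mismatch` substitutions per block and 5-150 residues between
#' consecutive blocks. The identity of the B block decides the call:
#' a GDD-carrying B block gives `rdrp_core`, a YxDD-style B block gives
#' `rt_core`. When both variants can complete a triple the higher-scoring
#' one wins, with ties resolved to `rt_core` (conservative for RT
#' exclusion).
#'
#' @param sequence protein sequence string.
#' @param max_mismatch maximum substitutions tolerated per 6-residue block.
#' @return list with `core` (`"rdrp_core"`, `"rt_core"` or `"none"`) and
#'   `score` (18 minus total mismatches; `NA` when no core found).
#' @export
detect_palmprint <- function(sequence, max_mismatch = 1) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  hits_a <- .motif_hits(chars, PALM_A, max_mismatch)
  hits_c <- .motif_hits(chars, PALM_C, max_mismatch)
  best <- list(core = "none", score = NA_real_)
  if (nrow(hits_a) == 0 || nrow(hits_c) == 0) return(best)
  for (variant in c("rt_core", "rdrp_core")) {
    motif_b <- if (variant == "rdrp_core") PALM_B_RDRP else PALM_B_RT
    hits_b <- .motif_hits(chars, motif_b, max_mismatch)
    if (nrow(hits_b) == 0) next
    for (ib in seq_len(nrow(hits_b))) {
      b <- hits_b$pos[ib]
      ok_a <- hits_a$pos + 6L + PALM_GAP_RANGE[1] <= b &
        hits_a$pos + 6L + PALM_GAP_RANGE[2] >= b
      ok_c <- hits_c$pos >= b + 6L + PALM_GAP_RANGE[1] &
        hits_c$pos <= b + 6L + PALM_GAP_RANGE[2]
      if (!any(ok_a) || !any(ok_c)) next
      score <- 18 - (min(hits_a$mm[ok_a]) + hits_b$mm[ib] + min(hits_c$mm[ok_c]))
      ## strict > keeps rt_core on ties (rt is checked first)
      if (best$core == "none" || score > best$score) {
        best <- list(core = variant, score = score)
      }
    }
  }
  best
}
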