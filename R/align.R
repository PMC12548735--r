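## Gapped Karlin-Altschul constants for the supported scoring systems
## (published values for BLOSUM62 with gap open 11 / extend 1).
.KA_CONSTANTS <- list(
  BLOSUM62 = c(lambda = 0.267, K = 0.041)
)

#' Local alignment bit score between two proteins
#'
#' Smith-Waterman optimal local alignment (affine gaps) via
#' `Biostrings::pairwiseAlignment`, converted to bits with the matrix's
#' gapped Karlin-Altschul constants: `bits = (lambda * S - ln K) / ln 2`.
#' This is the package's internal surrogate for DIAMOND/BLASTP evidence.
#' The raw score is floored at 0 (the Smith-Waterman floor) and returned
#' as attribute `raw_score`.
#'
#' @param query,subject protein sequence strings.
#' @param matrix substitution matrix name (only `"BLOSUM62"` is registered).
#' @param gap_open,gap_extend affine gap penalties (positive costs; a gap of
#'   length L costs `gap_open + L * gap_extend`).
#' @return bit score (double) with attribute `raw_score`.
#' @export
local_align_bits <- function(query, subject, matrix = "BLOSUM62",
                             gap_open = 11, gap_extend = 1) {
  if (!matrix %in% names(.KA_CONSTANTS)) {
    stop("unknown substitution matrix: ", matrix)
  }
  stopifnot(gap_open >= 0, gap_extend >= 0)
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend,
    scoreOnly = TRUE
  )
  s <- max(0, s)
  ka <- .KA_CONSTANTS[[matrix]]
  bits <- (ka[["lambda"]] * s - log(ka[["K"]])) / log(2)
  attr(bits, "raw_score") <- s
  bits
}

#' Best local-alignment bits of a query against a panel of subjects
#'
#' @param query protein sequence string.
#' @param panel tibble with `record_id` and `sequence`.
#' @param ... passed to [local_align_bits()].
#' @return list with `bits` (best bit score) and `subject_id`.
#' @export
best_panel_hit <- function(query, panel, matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1) {
  if (nrow(panel) == 0) return(list(bits = NA_real_, subject_id = NA_character_))
  if (!matrix %in% names(.KA_CONSTANTS)) {
    stop("unknown substitution matrix: ", matrix)
  }
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(panel$sequence), Biostrings::AAString(query),
    type = "local", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
  s <- pmax(0, s)
  ka <- .KA_CONSTANTS[[matrix]]
  bits <- (ka[["lambda"]] * s - log(ka[["K"]])) / log(2)
  i <- which.max(bits)
  list(bits = bits[[i]], subject_id = panel$record_id[i])
}
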