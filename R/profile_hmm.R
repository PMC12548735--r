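#' Construct a profile HMM from explicit parameters
#'
#' Low-level constructor; most users should use [build_profile()]. Transition
#' vectors have length `M - 1` and describe the move from column `j` to
#' `j + 1`.
#'
#' @param name profile name.
#' @param match_emissions `M x A` matrix of match emission probabilities
#'   (columns named by the alphabet).
#' @param transitions list with numeric vectors `MM, MI, MD, IM, II, DM, DD`.
#' @param background length-`A` named background distribution; also used as
#'   the (background-tied) insert emission distribution.
#' @return a `ProfileHMM` object.
#' @export
profile_hmm <- function(name, match_emissions, transitions, background) {
  match_emissions <- as.matrix(match_emissions)
  obj <- structure(list(
    name = name,
    M = nrow(match_emissions),
    alphabet = names(background),
    match_emissions = match_emissions,
    insert_emissions = background,
    transitions = transitions,
    background = background
  ), class = "ProfileHMM")
  validate_profile(obj)
  obj
}

#' @export
print.ProfileHMM <- function(x, ...) {
  cat(sprintf("ProfileHMM '%s': %d match states, %d-letter alphabet\n",
              x$name, x$M, length(x$alphabet)))
  invisible(x)
}

#' Validate profile HMM invariants
#' @param profile a `ProfileHMM`.
#' @return the profile, invisibly; errors when a probability row does not
#'   normalize, any probability is non-positive, or `M < 1`.
#' @export
validate_profile <- function(profile) {
  stopifnot(inherits(profile, "ProfileHMM"))
  if (profile$M < 1) stop("profile must have at least one match state")
  if (any(profile$match_emissions <= 0) || any(profile$background <= 0)) {
    stop("all probabilities must be > 0 after pseudocounts")
  }
  if (any(abs(rowSums(profile$match_emissions) - 1) > 1e-9)) {
    stop("match emission row does not sum to 1")
  }
  if (abs(sum(profile$background) - 1) > 1e-9) {
    stop("background does not sum to 1")
  }
  tr <- profile$transitions
  if (profile$M > 1) {
    sums <- rbind(tr$MM + tr$MI + tr$MD, tr$IM + tr$II, tr$DM + tr$DD)
    if (any(abs(sums - 1) > 1e-9)) stop("transition triple does not sum to 1")
    if (any(unlist(tr) <= 0)) stop("all probabilities must be > 0 after pseudocounts")
  }
  invisible(profile)
}

## Henikoff position-based sequence weights, normalized to total weight 1
## (per-column Henikoff contributions always sum to 1, so averaging over
## columns keeps the total at 1 up to gap effects; we renormalize exactly).
henikoff_weights <- function(msa) {
  n <- nrow(msa)
  w <- numeric(n)
  used <- 0L
  for (j in seq_len(ncol(msa))) {
    col <- msa[, j]
    res <- col != "-" & col != "X"
    if (!any(res)) next
    counts <- table(col[res])
    r <- length(counts)
    w[res] <- w[res] + 1 / (r * as.numeric(counts[col[res]]))
    used <- used + 1L
  }
  if (used == 0L) stop("alignment has no residue-bearing columns")
  w <- w / used
  w / sum(w)
}

## prior over transition classes used to spread the Laplace mass alpha;
## a flat split would put half the mass on indels, which no real profile
## builder does
.TRANS_PRIOR <- list(M = c(MM = 0.85, MI = 0.075, MD = 0.075),
                     I = c(IM = 0.80, II = 0.20),
                     D = c(DM = 0.80, DD = 0.20))

#' Build a profile HMM from a multiple sequence alignment
#'
#' Match columns are the alignment columns with gap fraction <= 0.5.
#' Emissions are Henikoff position-based weighted counts smoothed with
#' `alpha * background` pseudocounts and divided by (weight sum + alpha);
#' transitions are weighted counts from the observed per-row state paths
#' with Laplace mass `alpha` spread proportionally to a canonical
#' transition prior. Insert emissions are tied to the background.
#'
#' @param msa character matrix (see [read_msa()]) or named character vector
#'   of aligned rows; at least two rows of equal length.
#' @param name profile name.
#' @param pseudocount_alpha total pseudocount mass (default 1).
#' @param background named background distribution; default Robinson-Robinson
#'   frequencies over the 20 amino acids.
#' @return a `ProfileHMM`.
#' @export
build_profile <- function(msa, name, pseudocount_alpha = 1,
                          background = ROBINSON_BG) {
  if (!is.matrix(msa)) msa <- msa_matrix(msa)
  if (nrow(msa) < 2) stop("alignment must have at least 2 rows")
  alphabet <- names(background)
  bad <- setdiff(unique(as.vector(msa)), c(alphabet, "-", "X"))
  if (length(bad)) stop("invalid alignment character(s): ",
                        paste(bad, collapse = ", "))
  gap_frac <- colMeans(msa == "-")
  match_cols <- which(gap_frac <= 0.5)
  if (!length(match_cols)) stop("alignment has zero match columns")
  M <- length(match_cols)
  w <- henikoff_weights(msa)
  a <- pseudocount_alpha

  emis <- matrix(0, nrow = M, ncol = length(alphabet),
                 dimnames = list(NULL, alphabet))
  for (k in seq_len(M)) {
    col <- msa[, match_cols[k]]
    res <- col %in% alphabet
    counts <- vapply(alphabet, function(ch) sum(w[col == ch & res]), 0)
    emis[k, ] <- (counts + a * background) / (sum(w[res]) + a)
    emis[k, ] <- emis[k, ] / sum(emis[k, ])
  }

  ## weighted transition counts along each row's state path
  nm <- max(M - 1, 0)
  cnt <- list(MM = numeric(nm), MI = numeric(nm), MD = numeric(nm),
              IM = numeric(nm), II = numeric(nm),
              DM = numeric(nm), DD = numeric(nm))
  is_match <- seq_len(ncol(msa)) %in% match_cols
  col_idx <- cumsum(is_match)  # profile column index at or before column j
  if (M > 1) {
    for (r in seq_len(nrow(msa))) {
      prev <- NULL  # c(type, j)
      for (jc in seq_len(ncol(msa))) {
        ch <- msa[r, jc]
        state <- if (is_match[jc]) {
          c(if (ch == "-") "D" else "M", col_idx[jc])
        } else if (ch != "-") {
          c("I", col_idx[jc])
        } else NULL
        if (!is.null(state)) {
          if (!is.null(prev)) {
            key <- paste0(prev[1], state[1])
            jfrom <- as.integer(prev[2])
            if (key %in% names(cnt) && jfrom >= 1 && jfrom <= nm) {
              cnt[[key]][jfrom] <- cnt[[key]][jfrom] + w[r]
            }
          }
          prev <- state
        }
      }
    }
  }
  pr <- .TRANS_PRIOR
  trans <- list()
  denomM <- cnt$MM + cnt$MI + cnt$MD + a
  trans$MM <- (cnt$MM + a * pr$M["MM"]) / denomM
  trans$MI <- (cnt$MI + a * pr$M["MI"]) / denomM
  trans$MD <- (cnt$MD + a * pr$M["MD"]) / denomM
  denomI <- cnt$IM + cnt$II + a
  trans$IM <- (cnt$IM + a * pr$I["IM"]) / denomI
  trans$II <- (cnt$II + a * pr$I["II"]) / denomI
  denomD <- cnt$DM + cnt$DD + a
  trans$DM <- (cnt$DM + a * pr$D["DM"]) / denomD
  trans$DD <- (cnt$DD + a * pr$D["DD"]) / denomD
  trans <- lapply(trans, unname)

  profile_hmm(name, emis, trans, background)
}

## match emission log-odds matrix (M x n) for a sequence; characters outside
## the alphabet (e.g. X) get log-odds 0 throughout
.prof_lod <- function(profile, sequence) {
  chars <- strsplit(sequence, "")[[1]]
  idx <- match(chars, profile$alphabet)
  L <- log(profile$match_emissions) -
    matrix(log(profile$background), nrow = profile$M,
           ncol = length(profile$alphabet), byrow = TRUE)
  out <- matrix(0, nrow = profile$M, ncol = length(chars))
  known <- !is.na(idx)
  out[, known] <- L[, idx[known], drop = FALSE]
  out
}

.log_trans <- function(profile) {
  lapply(profile$transitions, log)
}

#' Best local alignment bit score of a sequence against a profile (Viterbi)
#'
#' Local (Smith-Waterman-style) alignment with uniform entry over match
#' states and free exit; the score is the log2 odds of the best state path
#' against the i.i.d. background null. This is the package's "domain score":
#' the best single envelope, no multi-domain chaining.
#'
#' @param profile a `ProfileHMM`.
#' @param sequence protein sequence string.
#' @param record_id optional id carried into the hit.
#' @return one-row tibble: `record_id`, `profile`, `bits`, `env_start`,
#'   `env_end` (0-based half-open on the query), `mode`.
#' @export
viterbi_bits <- function(profile, sequence, record_id = NA_character_) {
  stopifnot(inherits(profile, "ProfileHMM"), nzchar(sequence))
  lt <- .log_trans(profile)
  res <- phmm_viterbi_cpp(.prof_lod(profile, sequence),
                          lt$MM, lt$MI, lt$MD, lt$IM, lt$II, lt$DM, lt$DD)
  tibble::tibble(record_id = record_id, profile = profile$name,
                 bits = res$score_nats / log(2),
                 env_start = res$env_start - 1L, env_end = res$env_end,
                 mode = "viterbi")
}

#' Forward (all-paths) bit score of a sequence against a profile
#'
#' As [viterbi_bits()] but summing over all local alignments (log-sum-exp);
#' always >= the Viterbi score. The envelope is reported as the whole query.
#'
#' @inheritParams viterbi_bits
#' @return one-row tibble as in [viterbi_bits()], `mode = "forward"`.
#' @export
forward_bits <- function(profile, sequence, record_id = NA_character_) {
  stopifnot(inherits(profile, "ProfileHMM"), nzchar(sequence))
  lt <- .log_trans(profile)
  nats <- phmm_forward_cpp(.prof_lod(profile, sequence),
                           lt$MM, lt$MI, lt$MD, lt$IM, lt$II, lt$DM, lt$DD)
  tibble::tibble(record_id = record_id, profile = profile$name,
                 bits = nats / log(2),
                 env_start = 0L, env_end = nchar(sequence),
                 mode = "forward")
}

#' Scan records against a set of profiles with a bit-score gate
#'
#' For each record the best Viterbi hit across all profiles is kept; records
#' whose best score is below `gate_bits` are omitted (the gate is inclusive:
#' a score exactly at the gate is retained). Ties between profiles are broken
#' by lexicographic profile name and logged.
#'
#' @param records tibble with `record_id` and `sequence`.
#' @param profiles list of `ProfileHMM` objects.
#' @param gate_bits minimum retained domain score (default 25, >= 0).
#' @return tibble of best hits: `record_id`, `profile`, `bits`, `env_start`,
#'   `env_end`, `mode`.
#' @export
scan_profiles <- function(records, profiles, gate_bits = 25) {
  if (length(profiles) == 0) stop("empty profile list")
  stopifnot(gate_bits >= 0)
  pnames <- vapply(profiles, function(p) p$name, "")
  ord <- order(pnames)
  profiles <- profiles[ord]
  hits <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    per <- purrr::map_dfr(profiles, viterbi_bits,
                          sequence = records$sequence[i],
                          record_id = records$record_id[i])
    best <- which.max(per$bits)
    n_tied <- sum(abs(per$bits - per$bits[best]) < 1e-12)
    if (n_tied > 1) {
      rs_log("scan tie for %s: %d profiles at %.3f bits, keeping '%s'",
             records$record_id[i], n_tied, per$bits[best], per$profile[best])
      best <- which(abs(per$bits - max(per$bits)) < 1e-12)[1]
    }
    per[best, ]
  })
  kept <- hits[hits$bits >= gate_bits, , drop = FALSE]
  rs_log_funnel(sprintf("scan (gate %.1f bits)", gate_bits),
                nrow(records), nrow(kept))
  kept
}

#' Align sequences to a profile's match columns
#'
#' Maps each sequence onto the profile's match states via the Viterbi path,
#' yielding an implicit multiple alignment over the `M` match columns (the
#' profile-anchored analogue of `hmmalign`). Insert-state residues are
#' dropped; unaligned match columns are gaps.
#'
#' @param profile a `ProfileHMM`.
#' @param records tibble with `record_id` and `sequence`.
#' @return character matrix, rows named by `record_id`, `M` columns.
#' @export
profile_align <- function(profile, records) {
  lt <- .log_trans(profile)
  out <- matrix("-", nrow = nrow(records), ncol = profile$M,
                dimnames = list(records$record_id, NULL))
  for (i in seq_len(nrow(records))) {
    chars <- strsplit(records$sequence[i], "")[[1]]
    res <- phmm_viterbi_cpp(.prof_lod(profile, records$sequence[i]),
                            lt$MM, lt$MI, lt$MD, lt$IM, lt$II, lt$DM, lt$DD)
    aligned <- res$match_path > 0
    out[i, aligned] <- chars[res$match_path[aligned]]
  }
  out
}
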