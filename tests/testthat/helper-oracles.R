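## Independent oracles used to check the dynamic-programming implementations.
## These enumerate explicitly and share no code with the package internals.

options(rdrpscreen.verbose = FALSE)

## ---- profile-HMM path enumeration ----------------------------------------
## Enumerates every local state path (entry -log(M) into any match state,
## free exit from any match state) and returns all path log-odds in nats.
## Transition vectors are probabilities indexed by the source column.
enumerate_path_scores <- function(profile, sequence) {
  M <- profile$M
  lod <- log(profile$match_emissions) -
    matrix(log(profile$background), nrow = M,
           ncol = length(profile$background), byrow = TRUE)
  idx <- match(strsplit(sequence, "")[[1]], profile$alphabet)
  n <- length(idx)
  tr <- lapply(profile$transitions, log)
  scores <- c()
  emit <- function(j, i) lod[j, idx[i]]

  recurse <- function(state, i, j, acc) {
    if (state == "M") {
      scores <<- c(scores, acc)  # exit option
      if (j < M) {
        if (i < n) recurse("M", i + 1, j + 1, acc + tr$MM[j] + emit(j + 1, i + 1))
        if (i < n) recurse("I", i + 1, j, acc + tr$MI[j])
        recurse("D", i, j + 1, acc + tr$MD[j])
      }
    } else if (state == "I") {
      if (i < n) {
        recurse("I", i + 1, j, acc + tr$II[j])
        if (j < M) recurse("M", i + 1, j + 1, acc + tr$IM[j] + emit(j + 1, i + 1))
      }
    } else { # D at column j
      if (j < M) {
        if (i < n) recurse("M", i + 1, j + 1, acc + tr$DM[j] + emit(j + 1, i + 1))
        recurse("D", i, j + 1, acc + tr$DD[j])
      }
    }
  }
  for (i0 in seq_len(n)) {
    for (j0 in seq_len(M)) {
      recurse("M", i0, j0, -log(M) + emit(j0, i0))
    }
  }
  scores
}

oracle_viterbi_bits <- function(profile, sequence) {
  max(enumerate_path_scores(profile, sequence)) / log(2)
}

oracle_forward_bits <- function(profile, sequence) {
  s <- enumerate_path_scores(profile, sequence)
  m <- max(s)
  (m + log(sum(exp(s - m)))) / log(2)
}

## ---- Smith-Waterman (Gotoh) oracle ---------------------------------------
## Textbook affine-gap local alignment recurrence in plain R, independent of
## the Biostrings implementation. Gap of length L costs open + L * extend.
oracle_sw_score <- function(x, y, submat, gap_open, gap_extend) {
  xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
  n <- length(xs); m <- length(ys)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in y (vertical)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in x (horizontal)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i, j + 1] - gap_open - gap_extend,
                             E[i, j + 1] - gap_extend)
      F[i + 1, j + 1] <- max(H[i + 1, j] - gap_open - gap_extend,
                             F[i + 1, j] - gap_extend)
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + submat[xs[i], ys[j]],
                             E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

## ---- misc small oracles --------------------------------------------------
## longest ATG-initiated ORF by regex over all six frame translations
oracle_longest_orf_aa <- function(nt) {
  rc <- function(s) paste0(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                           collapse = "")
  translate1 <- function(s) {
    n <- nchar(s) %/% 3
    if (n == 0) return("")
    paste0(unname(Biostrings::GENETIC_CODE[
      substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))]), collapse = "")
  }
  best <- 0L
  for (s in c(nt, rc(nt))) {
    for (off in 0:2) {
      aa <- translate1(substr(s, off + 1, nchar(s)))
      hits <- regmatches(aa, gregexpr("M[^*]*", aa))[[1]]
      if (length(hits)) best <- max(best, max(nchar(hits)))
    }
  }
  best
}

## unrooted bipartitions of a tree as a canonical set of leaf-subset keys
oracle_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  n <- length(tips)
  keys <- character(0)
  nt <- length(tree$tip.label)
  for (node in (nt + 1):(nt + tree$Nnode)) {
    below <- tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
    if (length(below) <= 1 || length(below) >= n - 1) next
    side <- sort(below)
    other <- setdiff(tips, side)
    key <- if (side[1] < other[1]) paste(side, collapse = "|")
    else paste(other, collapse = "|")
    keys <- c(keys, key)
  }
  unique(keys)
}

## random additive tree and its exact leaf-to-leaf distance matrix
random_additive_case <- function(n_taxa) {
  tree <- ape::rtree(n_taxa, br = function(k) runif(k, 0.05, 1))
  list(tree = tree, D = ape::cophenetic.phylo(tree))
}
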