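## Shared fixtures: toy alphabets, profiles and records built in code.

toy_bg2 <- setNames(c(0.5, 0.5), c("A", "B"))
toy_bg3 <- setNames(c(1, 1, 1) / 3, c("A", "B", "C"))
uniform_bg20 <- setNames(rep(0.05, 20), rdrpscreen:::AA20)

## a random valid toy profile over a small alphabet (rows normalized)
random_toy_profile <- function(M, bg = toy_bg2, name = "toy") {
  A <- length(bg)
  emis <- matrix(rexp(M * A), nrow = M, dimnames = list(NULL, names(bg)))
  emis <- emis / rowSums(emis)
  rnorm3 <- function(n) {
    x <- matrix(rexp(3 * n), ncol = 3)
    x / rowSums(x)
  }
  rnorm2 <- function(n) {
    x <- matrix(rexp(2 * n), ncol = 2)
    x / rowSums(x)
  }
  nm <- max(M - 1, 0)
  m3 <- rnorm3(nm); i2 <- rnorm2(nm); d2 <- rnorm2(nm)
  profile_hmm(name, emis,
              list(MM = m3[, 1], MI = m3[, 2], MD = m3[, 3],
                   IM = i2[, 1], II = i2[, 2],
                   DM = d2[, 1], DD = d2[, 2]),
              bg)
}

## peaked profile emitting `pattern` with high probability, minimal indels
peaked_profile <- function(pattern, bg = uniform_bg20, peak = 0.9,
                           indel = 0.01, name = "peaked") {
  chars <- strsplit(pattern, "")[[1]]
  M <- length(chars)
  emis <- matrix((1 - peak) / (length(bg) - 1), nrow = M, ncol = length(bg),
                 dimnames = list(NULL, names(bg)))
  for (k in seq_len(M)) emis[k, chars[k]] <- peak
  nm <- max(M - 1, 0)
  profile_hmm(name, emis,
              list(MM = rep(1 - 2 * indel, nm), MI = rep(indel, nm),
                   MD = rep(indel, nm),
                   IM = rep(0.9, nm), II = rep(0.1, nm),
                   DM = rep(0.9, nm), DD = rep(0.1, nm)),
              bg)
}

random_protein <- function(n) {
  paste0(sample(rdrpscreen:::AA20, n, replace = TRUE), collapse = "")
}

## small record tibble
toy_records <- function(seqs, ids = sprintf("REC%02d", seq_along(seqs)),
                        titles = rep("hypothetical protein", length(seqs))) {
  tibble::tibble(record_id = ids, title = titles, sequence = seqs)
}

## evidence bundle builder with absent channels by default
bundle <- function(record_id = "X1", foldseek = NA_real_, palm = "none",
                   blast = NA_real_, blast_rt = NA_real_, tree = NA_real_,
                   hmmer = NA_real_) {
  tibble::tibble(record_id = record_id, foldseek_bits = foldseek,
                 palmprint = palm, blast_rdrp_bits = blast,
                 blast_rt_bits = blast_rt, tree_distance = tree,
                 hmmer_bits = hmmer)
}

small_corpus <- function(seed = 7, n1 = 20, n2 = 20, n3 = 10, n4 = 10, n5 = 10) {
  generate_corpus(corpus_config(n_rdrp_intact = n1, n_rt = n2, n_eve = n3,
                                n_nearmiss = n4, n_unrelated = n5,
                                seed = seed))
}
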