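test_that("local alignment bits behave like a similarity score", {
  set.seed(51)
  q <- random_protein(100)
  shuffled <- paste0(sample(strsplit(q, "")[[1]]), collapse = "")
  self <- local_align_bits(q, q)
  expect_gt(self, local_align_bits(q, shuffled))
  expect_error(local_align_bits(q, q, matrix = "PAM999"), "unknown")
})

test_that("raw Smith-Waterman scores match the Gotoh oracle on short pairs", {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  set.seed(52)
  for (i in 1:40) {
    x <- random_protein(sample(3:8, 1))
    y <- random_protein(sample(3:8, 1))
    got <- attr(local_align_bits(x, y, gap_open = 2, gap_extend = 2),
                "raw_score")
    expect_equal(got, oracle_sw_score(x, y, BLOSUM62, 2, 2),
                 info = paste(x, y))
  }
})

test_that("non-matching sequences floor at raw score 0", {
  ## negative-scoring residue pair everywhere: W vs G scores -2 in BLOSUM62
  bits <- local_align_bits("WWWWW", "GGGGG")
  expect_equal(attr(bits, "raw_score"), 0)
})

test_that("dedup keeps non-RefSeq representatives and drops known RdRps", {
  recs <- tibble::tibble(
    record_id = c("XP_0001.1", "ABC123.1", "QQQ1.1", "KNOWN9.1"),
    sequence = c("MKVLA", "MKVLA", "GDDSV", "PPPPP"))
  out <- dedup_records(recs, known_rdrp_ids = "KNOWN9.1")
  expect_setequal(out$record_id, c("ABC123.1", "QQQ1.1"))

  all_unique <- tibble::tibble(record_id = c("A1", "B2"),
                               sequence = c("MK", "ML"))
  expect_equal(dedup_records(all_unique), all_unique)
})

test_that("integrate_evidence reproduces the printed worked examples", {
  ## all five criteria met
  r <- integrate_evidence(bundle(foldseek = 120, palm = "rdrp_core",
                                 blast = 60, tree = 0.8, hmmer = 70))
  expect_equal(r$n_met, 5L)
  expect_equal(r$verdict, "rdrp")

  ## exactly two criteria (blast, hmmer)
  r <- integrate_evidence(bundle(blast = 60, tree = 2.0, hmmer = 55))
  expect_true(r$crit_blast && r$crit_hmmer)
  expect_false(r$crit_tree)
  expect_equal(r$n_met, 2L)
  expect_equal(r$verdict, "rdrp")

  ## one criterion -> insufficient
  r <- integrate_evidence(bundle(hmmer = 80))
  expect_equal(r$n_met, 1L)
  expect_equal(r$verdict, "insufficient")

  ## RT-like palm core excludes regardless of other evidence
  r <- integrate_evidence(bundle(foldseek = 120, palm = "rt_core",
                                 blast = 60, tree = 0.8, hmmer = 70))
  expect_true(r$excluded_as_rt)
  expect_equal(r$verdict, "rt_like")

  ## RT blast exclusion needs the floor AND dominance over the RdRp score
  r <- integrate_evidence(bundle(blast = 60, blast_rt = 55, hmmer = 70))
  expect_false(r$excluded_as_rt)
  r <- integrate_evidence(bundle(blast = 40, blast_rt = 55, hmmer = 70))
  expect_true(r$excluded_as_rt)
})

test_that("printed thresholds are strict exactly as printed", {
  base <- function(...) integrate_evidence(bundle(...))
  expect_false(base(foldseek = 100, hmmer = 80)$crit_foldseek)  # >100 strict
  expect_true(base(foldseek = 100 + 1e-9, hmmer = 80)$crit_foldseek)
  expect_false(base(blast = 50, hmmer = 80)$crit_blast)         # >50 strict
  expect_false(base(tree = 1.5, hmmer = 80)$crit_tree)          # <1.5 strict
  expect_true(base(tree = 1.5 - 1e-9, hmmer = 80)$crit_tree)
  expect_false(base(hmmer = 50, tree = 0.5)$crit_hmmer)         # >50 strict
})

test_that("the 2-of-5 rule holds over all 32 satisfaction patterns", {
  good <- list(foldseek = 150, palm = "rdrp_core", blast = 80, tree = 0.5,
               hmmer = 90)
  for (mask in 0:31) {
    on <- as.logical(bitwAnd(mask, 2^(0:4)))
    b <- bundle(
      foldseek = if (on[1]) good$foldseek else NA_real_,
      palm = if (on[2]) good$palm else "none",
      blast = if (on[3]) good$blast else NA_real_,
      tree = if (on[4]) good$tree else NA_real_,
      hmmer = if (on[5]) good$hmmer else 1)  # keep >= 1 channel present
    r <- integrate_evidence(b)
    expect_equal(r$n_met, sum(on))
    expect_equal(r$verdict, if (sum(on) >= 2) "rdrp" else "insufficient",
                 info = paste("mask", mask))
  }
})

test_that("improving any single channel never flips rdrp to insufficient", {
  set.seed(53)
  for (i in 1:50) {
    b <- bundle(
      foldseek = if (runif(1) < 0.5) runif(1, 0, 200) else NA_real_,
      palm = sample(c("none", "rdrp_core"), 1),
      blast = if (runif(1) < 0.5) runif(1, 0, 100) else NA_real_,
      tree = if (runif(1) < 0.5) runif(1, 0, 3) else NA_real_,
      hmmer = runif(1, 0, 100))
    before <- integrate_evidence(b)$verdict
    if (before != "rdrp") next
    for (ch in c("foldseek_bits", "blast_rdrp_bits", "hmmer_bits")) {
      b2 <- b; b2[[ch]] <- (if (is.na(b[[ch]])) 0 else b[[ch]]) + 100
      expect_equal(integrate_evidence(b2)$verdict, "rdrp")
    }
    b2 <- b; b2$tree_distance <- 0.01
    expect_equal(integrate_evidence(b2)$verdict, "rdrp")
  }
})

test_that("malformed bundles are rejected", {
  expect_error(integrate_evidence(tibble::tibble(foldseek_bits = 1)),
               "record_id")
  expect_error(integrate_evidence(bundle()), "no evidence channel")
  expect_error(integrate_evidence(bundle(palm = "weird", hmmer = 5)),
               "palmprint")
})

test_that("evidence_from_tables assembles channels and validates keys", {
  recs <- toy_records(c("MKVLA", "GDDSV", "PQRST"))
  hits <- tibble::tibble(record_id = c("REC01", "REC02"), bits = c(60, 30))
  fs <- tibble::tibble(record_id = "REC01", bits = 150)

  b <- evidence_from_tables(recs, hits, foldseek = fs)
  expect_equal(b$foldseek_bits, c(150, NA))
  expect_equal(b$palmprint, c("none", "none"))
  expect_true(all(is.na(b$tree_distance)))

  dup <- tibble::tibble(record_id = c("REC01", "REC01"),
                        core = c("rdrp_core", "none"))
  expect_error(evidence_from_tables(recs, hits, palm = dup), "duplicate")
  ghost <- tibble::tibble(record_id = "NOPE", bits = 1)
  expect_error(evidence_from_tables(recs, hits, foldseek = ghost), "unknown")
})

test_that("palmprint detector separates GDD and YxDD cores", {
  cons <- rdrpscreen:::builtin_consensi()
  rdrp_seq <- paste0(cons$rdrp, collapse = "")
  rt_seq <- paste0(cons$rt, collapse = "")
  expect_equal(detect_palmprint(rdrp_seq)$core, "rdrp_core")
  expect_equal(detect_palmprint(rt_seq)$core, "rt_core")
  expect_equal(detect_palmprint(random_protein(300))$core, "none")
})
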