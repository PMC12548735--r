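test_that("near-miss band is [10, 25) exactly", {
  scores <- tibble::tibble(record_id = sprintf("R%d", 1:5),
                           bits = c(9.99, 10, 24.999, 25, 40))
  nm <- select_near_miss(scores)
  expect_equal(nm$record_id, c("R2", "R3"))
  expect_equal(nrow(select_near_miss(scores[0, ])), 0)

  ## three-way partition of the score axis: below / near-miss / candidate
  in_nm <- scores$bits >= 10 & scores$bits < 25
  in_cand <- scores$bits >= 25
  expect_false(any(in_nm & in_cand))
  expect_equal(sum(!in_nm & !in_cand), 1)  # only the 9.99 score
})

test_that("term enrichment reproduces the printed DoxX arithmetic", {
  res <- term_enrichment(c(doxx = 785), 577704, c(doxx = 2), 499240)
  oracle <- log2((785 / 577704) / (2 / 499240))
  expect_equal(res$log2_fold_change, oracle, tolerance = 1e-12)
  expect_equal(round(res$log2_fold_change, 2), 8.41)
})

test_that("term enrichment handles equal frequencies, zeros and ranking", {
  res <- term_enrichment(c(t1 = 10), 1000, c(t1 = 20), 2000)
  expect_equal(res$log2_fold_change, 0)

  ## haldane: 0.5 added to both counts when either is zero
  res0 <- term_enrichment(c(t1 = 8), 100, c(t1 = 0), 200)
  expect_true(is.finite(res0$log2_fold_change))
  expect_equal(res0$log2_fold_change, log2((8.5 / 100) / (0.5 / 200)))
  expect_equal(nrow(term_enrichment(c(t1 = 8), 100, c(t1 = 0), 200,
                                    zero_policy = "omit")), 0)

  ## antisymmetry when no zero-policy fires
  a <- term_enrichment(c(x = 5, y = 9), 100, c(x = 9, y = 5), 100)
  b <- term_enrichment(c(x = 9, y = 5), 100, c(x = 5, y = 9), 100)
  expect_equal(sort(a$log2_fold_change), sort(-b$log2_fold_change))

  ## ranked descending, ties by larger test count then term
  res <- term_enrichment(c(a = 4, b = 8, c = 4), 100,
                         c(a = 2, b = 4, c = 2), 100)
  expect_equal(res$term, c("b", "a", "c"))

  ## a term absent from both sets is omitted
  res <- term_enrichment(c(a = 1, ghost = 0), 10, c(a = 1), 10)
  expect_false("ghost" %in% res$term)
})

make_annotations <- function(ids, blast, cdd = NULL, palm = NULL,
                             hmmer = NULL) {
  if (is.null(cdd)) {
    cdd <- tibble::tibble(record_id = ids, term_id = "cd00001",
                          rna_virus_exclusive = FALSE)
  }
  list(records = ids, blast = blast, cdd = cdd, palmprint = palm,
       hmmer = hmmer)
}

five_hits <- function(id, bits = 51, pid = 41, len = 101,
                      class = "non_rna_viral", n = 5) {
  tibble::tibble(record_id = id, subject_id = sprintf("S%d", seq_len(n)),
                 bits = bits, pct_identity = pid, aln_length = len,
                 subject_class = class)
}

test_that("control sets follow the NC/NM criteria at their boundaries", {
  ## all thresholds at +1 of the boundary -> NC
  ann <- make_annotations("A1", five_hits("A1"))
  suppressWarnings(sets <- build_control_sets(ann, set_size = 10))
  expect_equal(sets$nc, "A1")
  expect_equal(sets$nm, character(0))

  ## one hit at bits exactly 50 is non-qualifying; only 4 remain -> rejected
  blast <- five_hits("A1")
  blast$bits[1] <- 50
  suppressWarnings(sets <- build_control_sets(make_annotations("A1", blast), 10))
  expect_equal(sets$nc, character(0))

  ## a domain score of 15 moves the record from NC to NM
  ann <- make_annotations("A1", five_hits("A1"),
                          hmmer = tibble::tibble(record_id = "A1", bits = 15))
  suppressWarnings(sets <- build_control_sets(ann, 10))
  expect_equal(sets$nm, "A1")
  expect_equal(sets$nc, character(0))

  ## any qualifying RNA-viral hit disqualifies
  blast <- dplyr::bind_rows(five_hits("A1"),
                            five_hits("A1", class = "rna_viral", n = 1))
  suppressWarnings(sets <- build_control_sets(make_annotations("A1", blast), 10))
  expect_equal(sets$nc, character(0))

  ## RNA-virus-exclusive CDD term disqualifies; no CDD at all disqualifies
  cdd_bad <- tibble::tibble(record_id = "A1", term_id = "cd_rdrp",
                            rna_virus_exclusive = TRUE)
  suppressWarnings(
    sets <- build_control_sets(make_annotations("A1", five_hits("A1"),
                                                cdd = cdd_bad), 10))
  expect_equal(sets$nc, character(0))

  ## palmprint RdRp hit disqualifies
  palm <- tibble::tibble(record_id = "A1", core = "rdrp_core")
  suppressWarnings(
    sets <- build_control_sets(make_annotations("A1", five_hits("A1"),
                                                palm = palm), 10))
  expect_equal(sets$nc, character(0))
})

test_that("control sets are disjoint, deterministic and size-capped", {
  ids <- sprintf("R%02d", 1:20)
  blast <- dplyr::bind_rows(lapply(ids, five_hits))
  hm <- tibble::tibble(record_id = ids,
                       bits = rep(c(5, 15), 10))  # alternate NC / NM
  ann <- make_annotations(ids, blast, hmmer = hm)
  sets <- build_control_sets(ann, set_size = 5)
  expect_length(sets$nc, 5)
  expect_length(sets$nm, 5)
  expect_length(intersect(sets$nc, sets$nm), 0)
  expect_equal(sets$nc, sort(sets$nc))

  ## input order independence
  ann2 <- ann
  perm <- sample(nrow(blast))
  ann2$blast <- blast[perm, ]
  ann2$records <- rev(ids)
  expect_identical(build_control_sets(ann2, set_size = 5), sets)

  w <- testthat::capture_warnings(build_control_sets(ann, set_size = 50))
  expect_length(w, 2)  # both NC and NM fall short of the requested size
  expect_match(w, "only", all = TRUE)
})

test_that("mislabel flagging applies both thresholds and the taxon scope", {
  recs <- tibble::tibble(record_id = c("b1", "b2", "e1"),
                         taxon_label = c("bacteria", "bacteria", "eukaryota"))
  match_tbl <- tibble::tibble(
    record_id = c("b1", "b2", "e1"),
    virus_id = c("InfluenzaA", "DengueV", "HCV"),
    pct_identity = c(99, 84, 99),
    bits = c(450, 500, 450))
  fl <- flag_mislabelled(recs, match_tbl)
  expect_equal(fl$flagged, c(TRUE, FALSE, FALSE))
  expect_equal(fl$matched_virus[1], "InfluenzaA")
})

test_that("records-per-species medians match a sorting oracle", {
  counts <- c(a = 1, b = 10, c = 100)
  res <- records_per_species_proxy(counts, "c")
  expect_equal(res$median_all, 10)
  expect_equal(res$median_flagged, 100)

  res_all <- records_per_species_proxy(counts, names(counts))
  expect_equal(res_all$median_all, res_all$median_flagged)
  expect_true(is.na(records_per_species_proxy(counts, character(0))$median_flagged))

  set.seed(81)
  big <- setNames(rpois(1000, 20), sprintf("sp%04d", 1:1000))
  flagged <- sample(names(big), 137)
  res <- records_per_species_proxy(big, flagged)
  sort_median <- function(x) {
    s <- sort(x); n <- length(s)
    unname(if (n %% 2 == 1) s[(n + 1) / 2] else mean(s[n / 2 + 0:1]))
  }
  expect_equal(res$median_all, sort_median(big))
  expect_equal(res$median_flagged, sort_median(big[flagged]))
})
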