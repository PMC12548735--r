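#!/usr/bin/env Rscript

## Stage 7: near-miss enrichment and negative-control sets. Compares
## function terms between the near-miss band and a no-score control group,
## builds the NC (no score) and NM (near-miss) control sets, flags
## mislabelled bacteria-labelled records, and reports the
## records-per-species proxy.

suppressMessages(library(rdrpscreen))
set.seed(11)

records <- read_corpus("results/corpus/corpus.fasta",
                       "results/corpus/corpus.meta.tsv")
truth <- readr::read_tsv("results/corpus/corpus.truth.tsv",
                         show_col_types = FALSE)
scores <- readr::read_tsv("results/domain_scores.tsv", show_col_types = FALSE)

nearmiss <- select_near_miss(scores)
no_score <- records$record_id[!records$record_id %in%
                                scores$record_id[scores$bits >= 10]]

## synthetic function-term annotations: near-miss decoys lean towards a
## membrane-protein-like term, mirroring the kind of enrichment the real
## screen surfaces
term_pool <- c("membrane_protein", "kinase", "transporter", "hydrolase",
               "dna_binding")
assign_terms <- function(ids, bias) {
  probs <- c(bias, rep((1 - bias) / 4, 4))
  setNames(as.vector(table(factor(sample(term_pool, length(ids), TRUE, probs),
                                  levels = term_pool))), term_pool)
}
test_counts <- assign_terms(nearmiss$record_id, bias = 0.6)
ctrl_counts <- assign_terms(no_score, bias = 0.2)
enr <- term_enrichment(test_counts, length(nearmiss$record_id),
                       ctrl_counts, length(no_score))
readr::write_tsv(enr, "results/nearmiss_enrichment.tsv")
cat("top enriched terms in the near-miss band:\n")
print(as.data.frame(head(enr, 3)))

## NC/NM construction: neutral external channels, computed palmprint and
## domain-score channels
ids <- records$record_id
blast <- dplyr::bind_rows(lapply(ids, function(id) {
  tibble::tibble(record_id = id, subject_id = sprintf("S%d", 1:5),
                 bits = 60, pct_identity = 50, aln_length = 150,
                 subject_class = "non_rna_viral")
}))
palm <- tibble::tibble(
  record_id = ids,
  core = vapply(records$sequence, function(s) detect_palmprint(s)$core, ""))
ann <- list(records = ids, blast = blast,
            cdd = tibble::tibble(record_id = ids, term_id = "cd00001",
                                 rna_virus_exclusive = FALSE),
            palmprint = palm[palm$core != "none", ],
            hmmer = scores[, c("record_id", "bits")])
sets <- suppressWarnings(build_control_sets(ann, set_size = 20000))
writeLines(sets$nc, "results/nc_set.ids")
writeLines(sets$nm, "results/nm_set.ids")
intact <- truth$record_id[truth$class == "rdrp_intact"]
cat(sprintf("\nNC set: %d ids, NM set: %d ids, planted intact RdRps leaked: %d\n",
            length(sets$nc), length(sets$nm),
            length(intersect(c(sets$nc, sets$nm), intact))))

## mislabel flagging demo on constructed best-match evidence
bact <- records[records$taxon_label == "bacteria", ][1:4, ]
match_tbl <- tibble::tibble(
  record_id = bact$record_id,
  virus_id = c("influenza_A", "dengue_2", "HCV_1b", "AHSV"),
  pct_identity = c(99, 84, 92, 99),
  bits = c(450, 500, 410, 380))
fl <- flag_mislabelled(bact, match_tbl)
cat(sprintf("mislabel rule flags %d of %d bacteria-labelled examples\n",
            sum(fl$flagged), nrow(fl)))

counts <- setNames(rpois(300, 10) + 1, sprintf("virus%03d", 1:300))
flagged_sp <- names(sort(counts, decreasing = TRUE))[1:10]
proxy <- records_per_species_proxy(counts, flagged_sp)
cat(sprintf("records-per-species proxy: median all %.0f vs flagged %.0f\n",
            proxy$median_all, proxy$median_flagged))
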