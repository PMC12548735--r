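#!/usr/bin/env Rscript

## Stage 6: endogenous-viral-element signatures. Contrasts the DNA-source
## and RNA-source cohorts (contig scale, protein length), measures ORF
## degradation on the EVE pseudogenes (premature stops, frameshifts), and
## runs the shared-insertion-site test on worked alignment-block geometries.

suppressMessages(library(rdrpscreen))

records <- read_corpus("results/corpus/corpus.fasta",
                       "results/corpus/corpus.meta.tsv")
truth <- readr::read_tsv("results/corpus/corpus.truth.tsv",
                         show_col_types = FALSE)

sig <- cohort_signatures(records)
print(as.data.frame(sig))

## degradation metrics on the EVE pseudogene nucleotides
eves <- read_fasta("results/corpus/corpus.eve.fna")
metrics <- purrr::map_dfr(seq_len(nrow(eves)), function(i) {
  m <- degradation_metrics(eves$sequence[i])
  orf <- longest_orf(eves$sequence[i])
  tibble::tibble(record_id = eves$record_id[i],
                 stops_per_100_codons = m$stops_per_100_codons,
                 frameshift_flag = m$frameshift_flag,
                 longest_orf_aa = orf$aa_length)
})
readr::write_tsv(metrics, "results/eve_degradation.tsv")
cat(sprintf("\n%d EVE pseudogenes: %.1f%% with internal stops, %.1f%% flagged frameshifted\n",
            nrow(metrics), 100 * mean(metrics$stops_per_100_codons > 0),
            100 * mean(metrics$frameshift_flag)))
cat(sprintf("mean longest ORF in EVE pseudogenes: %.0f aa\n",
            mean(metrics$longest_orf_aa)))

## shared-insertion-site logic on the three canonical geometries
la <- eve_locus("genomeA", "chr1", 3000, 4500)
lb <- eve_locus("genomeB", "chr1", 3000, 4500)
blocks <- tibble::tibble(genome_a = "genomeA", chrom_a = "chr1",
                         start_a = 0, end_a = 9000,
                         genome_b = "genomeB", chrom_b = "chr1",
                         start_b = 0, end_b = 9000, pct_identity = 95)
cat("\ninsertion-site test:\n")
cat("  9000-nt block containing both loci ->",
    shared_insertion_site(la, lb, blocks), "\n")
blocks7 <- blocks; blocks7$end_a <- 7000; blocks7$end_b <- 7000
cat("  7000-nt block (below the >8000 nt rule) ->",
    shared_insertion_site(la, lb, blocks7), "\n")
blocks2 <- tibble::tibble(
  genome_a = c("genomeA", "genomeA"), chrom_a = c("chr1", "chr2"),
  start_a = c(0, 0), end_a = c(10000, 10000),
  genome_b = c("genomeB", "genomeB"), chrom_b = c("chr2", "chr1"),
  start_b = c(0, 0), end_b = c(10000, 10000), pct_identity = c(90, 90))
cat("  loci in long but non-corresponding blocks ->",
    shared_insertion_site(la, lb, blocks2), "\n")
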