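## Synthetic corpora with the statistical structure the screen assumes:
## intact RdRp proteins on kb-scale RNA contigs, RT/retroelement proteins,
## degraded EVE fragments on Mb-scale DNA chromosomes, near-miss decoys
## carrying one planted palm block, and unrelated background proteins.

## run expr under a temporary RNG state seeded with `seed`
with_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.pkg_cache <- new.env(parent = emptyenv())

## Built-in RdRp-like and RT-like seed alignments (synthetic stand-ins for
## the paper-external Pfam seed sets). Both consensuses are 260 aa and
## column-aligned to each other; the RT consensus shares the A and C palm
## blocks but carries the YxDD-style B block and ~40% overall identity.
.MOTIF_POS <- c(A = 101L, B = 141L, C = 181L)

builtin_consensi <- function() {
  if (!is.null(.pkg_cache$consensi)) return(.pkg_cache$consensi)
  cons <- with_rng(20220808L, {
    rdrp <- sample(AA20, 260, replace = TRUE, prob = ROBINSON_BG)
    plant <- function(x, pos, motif) {
      x[pos:(pos + 5L)] <- strsplit(motif, "")[[1]]
      x
    }
    rdrp <- plant(rdrp, .MOTIF_POS["A"], PALM_A)
    rdrp <- plant(rdrp, .MOTIF_POS["B"], PALM_B_RDRP)
    rdrp <- plant(rdrp, .MOTIF_POS["C"], PALM_C)
    rt <- rdrp
    motif_cols <- as.vector(outer(0:5, .MOTIF_POS, `+`))
    for (i in setdiff(seq_along(rt), motif_cols)) {
      if (runif(1) < 0.6) rt[i] <- sample(AA20, 1, prob = ROBINSON_BG)
    }
    rt <- plant(rt, .MOTIF_POS["B"], PALM_B_RT)
    list(rdrp = rdrp, rt = rt)
  })
  .pkg_cache$consensi <- cons
  cons
}

#' Built-in RdRp-like and RT-like seed alignments
#'
#' Deterministic synthetic seed MSAs (8 rows each, 260 aligned columns,
#' substitution-only divergence from a shared column frame) used as default
#' generative and scoring models throughout the package.
#'
#' @return list with character matrices `rdrp` and `rt`.
#' @export
builtin_seed_msas <- function() {
  if (!is.null(.pkg_cache$seed_msas)) return(.pkg_cache$seed_msas)
  cons <- builtin_consensi()
  msas <- with_rng(19920101L, {
    make_rows <- function(consensus, prefix) {
      rows <- vapply(seq_len(8), function(k) {
        x <- consensus
        mut <- runif(length(x)) < 0.12
        x[mut] <- sample(AA20, sum(mut), replace = TRUE, prob = ROBINSON_BG)
        paste0(x, collapse = "")
      }, "")
      names(rows) <- sprintf("%s_seed%02d", prefix, seq_len(8))
      msa_matrix(rows)
    }
    list(rdrp = make_rows(cons$rdrp, "RDRP"), rt = make_rows(cons$rt, "RT"))
  })
  .pkg_cache$seed_msas <- msas
  msas
}

#' Built-in default profiles built from the seed alignments
#'
#' `rdrp` and `rt` are single-clade profiles; `mixed` is built from both
#' seed sets pooled, emulating the mixed-seed Pfam-style profiles used for
#' the initial scan (which attract both RdRp and RT, hence the downstream
#' RT purge).
#'
#' @return list of three `ProfileHMM`s named `rdrp`, `rt` and `mixed`.
#' @export
builtin_profiles <- function() {
  if (!is.null(.pkg_cache$profiles)) return(.pkg_cache$profiles)
  msas <- builtin_seed_msas()
  p <- list(rdrp = build_profile(msas$rdrp, "RDRP_core"),
            rt = build_profile(msas$rt, "RT_core"),
            mixed = build_profile(rbind(msas$rdrp, msas$rt), "RDRP_mixed_seed"))
  .pkg_cache$profiles <- p
  p
}

.FAMILY_NAMES <- c("Alphafictiviridae", "Betafictiviridae",
                   "Gammafictiviridae")

#' Built-in subfamily consensus sequences
#'
#' Three deterministic subfamily consensuses derived from the RdRp seed
#' consensus (25% divergence outside the palm blocks), giving the known
#' reference panel real cluster structure for OTU placement and family
#' assignment.
#'
#' @return named character vector, one consensus per synthetic family.
#' @export
builtin_family_consensi <- function() {
  if (!is.null(.pkg_cache$family_consensi)) return(.pkg_cache$family_consensi)
  cons <- builtin_consensi()
  motif_cols <- as.vector(outer(0:5, .MOTIF_POS, `+`))
  out <- with_rng(17760704L, {
    vapply(.FAMILY_NAMES, function(f) {
      x <- cons$rdrp
      for (i in setdiff(seq_along(x), motif_cols)) {
        if (runif(1) < 0.25) x[i] <- sample(AA20, 1, prob = ROBINSON_BG)
      }
      paste0(x, collapse = "")
    }, "")
  })
  .pkg_cache$family_consensi <- out
  out
}

## point substitutions at `rate` per position, background replacement
mutate_protein <- function(sequence, rate) {
  x <- strsplit(sequence, "")[[1]]
  mut <- runif(length(x)) < rate
  x[mut] <- sample(AA20, sum(mut), replace = TRUE, prob = ROBINSON_BG)
  paste0(x, collapse = "")
}

#' Generate a panel of "known" reference proteins
#'
#' Known RdRp references are drawn around three subfamily consensuses (10%
#' divergence within a family), so the panel carries real cluster structure;
#' each family is one OTU. RT references are sampled from the RT profile.
#' These play the role of ICTV-classified viruses and annotated
#' retroelements.
#'
#' @param n_rdrp,n_rt panel sizes.
#' @param seed RNG seed.
#' @return tibble: `record_id`, `sequence`, `class` (`rdrp`/`rt`), `otu`,
#'   `family`, `known` (all `TRUE`).
#' @export
generate_reference_panel <- function(n_rdrp = 12, n_rt = 8, seed = 99L) {
  prof <- builtin_profiles()
  fams <- builtin_family_consensi()
  with_rng(seed, {
    fam_idx <- rep(seq_along(fams), length.out = n_rdrp)
    rdrp_seqs <- vapply(fam_idx, function(f) {
      mutate_protein(fams[[f]], 0.10)
    }, "")
    rt_seqs <- vapply(seq_len(n_rt), function(i) {
      sample_from_profile(prof$rt)
    }, "")
    tibble::tibble(
      record_id = c(sprintf("KNOWN_RDRP_%02d", seq_len(n_rdrp)),
                    sprintf("KNOWN_RT_%02d", seq_len(n_rt))),
      sequence = c(rdrp_seqs, rt_seqs),
      class = rep(c("rdrp", "rt"), c(n_rdrp, n_rt)),
      otu = c(sprintf("OTU-%d", fam_idx), rep("OTU-RT", n_rt)),
      family = c(names(fams)[fam_idx], rep("Retroelementa", n_rt)),
      known = TRUE
    )
  })
}

#' Corpus generator configuration
#'
#' Defaults state the emulated world: intact RdRps on RNA contigs with mean
#' contig length ~5.4 kb and mean protein length ~1228 aa; EVE fragments on
#' Mb-scale DNA (mean ~14.7 Mb) with degraded ORFs averaging ~480 aa;
#' a `mito_like` preset scales protein lengths to the 305 vs 774 aa regime.
#'
#' @param n_rdrp_intact,n_rt,n_eve,n_nearmiss,n_unrelated class counts.
#' @param seed integer seed; the whole corpus is a deterministic function of
#'   the config (same config, same bytes).
#' @param eve_params list: `fragment_fraction_range` in (0,1], `stop_rate`
#'   per codon, `frameshift_rate` per nt site.
#' @param length_models per-class lognormal length models, each
#'   `c(mean, sdlog)` (`mean` on the natural scale).
#' @param mito_like use the mitovirus-like length regime instead.
#' @return a validated `corpus_config` list.
#' @export
corpus_config <- function(n_rdrp_intact = 150, n_rt = 150, n_eve = 100,
                          n_nearmiss = 100, n_unrelated = 100, seed = 1L,
                          eve_params = list(
                            fragment_fraction_range = c(0.35, 0.75),
                            stop_rate = 6e-4,
                            frameshift_rate = 3e-4
                          ),
                          length_models = NULL, mito_like = FALSE) {
  counts <- c(n_rdrp_intact, n_rt, n_eve, n_nearmiss, n_unrelated)
  stopifnot(all(counts >= 0), length(seed) == 1)
  if (sum(counts) == 0) stop("config would generate zero records")
  stopifnot(length(eve_params$fragment_fraction_range) == 2,
            all(eve_params$fragment_fraction_range > 0),
            all(eve_params$fragment_fraction_range <= 1),
            eve_params$stop_rate >= 0, eve_params$stop_rate < 1,
            eve_params$frameshift_rate >= 0, eve_params$frameshift_rate < 1)
  if (is.null(length_models)) {
    length_models <- list(
      assembled_rna = c(mean = 5402, sdlog = 0.55),
      genomic_dna = c(mean = 14.7e6, sdlog = 1.0),
      protein_intact = c(mean = if (mito_like) 774 else 1228, sdlog = 0.30),
      protein_rt = c(mean = 1100, sdlog = 0.30),
      protein_other = c(mean = 400, sdlog = 0.50)
    )
  }
  structure(list(n_rdrp_intact = n_rdrp_intact, n_rt = n_rt, n_eve = n_eve,
                 n_nearmiss = n_nearmiss, n_unrelated = n_unrelated,
                 seed = as.integer(seed), eve_params = eve_params,
                 length_models = length_models, mito_like = mito_like),
            class = "corpus_config")
}

.rlnorm_mean <- function(n, model) {
  meanlog <- log(model[["mean"]]) - model[["sdlog"]]^2 / 2
  rlnorm(n, meanlog, model[["sdlog"]])
}

#' Sample a protein sequence from a profile HMM
#'
#' Stochastic walk through match/insert/delete states under the profile's
#' transition and emission probabilities, starting in the first match state
#' and ending after the last column. Uses the current RNG stream.
#'
#' @param profile a `ProfileHMM`.
#' @return amino-acid string.
#' @export
sample_from_profile <- function(profile) {
  validate_profile(profile)
  if (profile$M < 1) stop("profile of length 0")
  tr <- profile$transitions
  out <- character(0)
  j <- 1L
  state <- "M"
  repeat {
    if (state == "M") {
      out <- c(out, sample(profile$alphabet, 1,
                           prob = profile$match_emissions[j, ]))
      if (j == profile$M) break
      nxt <- sample(c("M", "I", "D"), 1,
                    prob = c(tr$MM[j], tr$MI[j], tr$MD[j]))
      if (nxt == "M") { j <- j + 1L } else if (nxt == "D") {
        j <- j + 1L; state <- "D"
      } else state <- "I"
    } else if (state == "I") {
      out <- c(out, sample(profile$alphabet, 1, prob = profile$insert_emissions))
      nxt <- sample(c("M", "I"), 1, prob = c(tr$IM[j], tr$II[j]))
      if (nxt == "M") { j <- j + 1L; state <- "M" }
    } else { # D
      if (j == profile$M) break
      nxt <- sample(c("M", "D"), 1, prob = c(tr$DM[j], tr$DD[j]))
      j <- j + 1L
      if (nxt == "M") state <- "M"
    }
  }
  paste0(out, collapse = "")
}

## uniform-synonymous-codon back-translation under the standard genetic code
.codon_table <- function() {
  if (is.null(.pkg_cache$codons)) {
    gc <- Biostrings::GENETIC_CODE
    .pkg_cache$codons <- split(names(gc), unname(gc))
  }
  .pkg_cache$codons
}

back_translate <- function(protein) {
  tab <- .codon_table()
  aas <- strsplit(protein, "")[[1]]
  codons <- vapply(aas, function(a) {
    opts <- tab[[a]]
    if (is.null(opts)) opts <- names(Biostrings::GENETIC_CODE)  # X: any codon
    if (length(opts) == 1) opts else sample(opts, 1)
  }, "")
  paste0(codons, collapse = "")
}

## translate frame 1 of a nucleotide string; trailing partial codon dropped
translate_nt <- function(nt) {
  n <- nchar(nt) %/% 3
  if (n == 0) return("")
  codons <- substring(nt, 3 * seq_len(n) - 2, 3 * seq_len(n))
  paste0(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

#' Degrade an intact protein into an EVE-like pseudogene
#'
#' Back-translates with uniform synonymous codons, truncates to a random
#' contiguous fraction of the gene, injects premature stop codons (per
#' codon) and single-nucleotide indels (per site), and emits the longest
#' surviving translated fragment as the protein record, emulating the
#' stop-codon-riddled, frameshifted ORFs of ancient endogenous insertions.
#'
#' @param sequence intact protein sequence.
#' @param eve_params list with `fragment_fraction_range`, `stop_rate`,
#'   `frameshift_rate` (see [corpus_config()]).
#' @param min_len minimum surviving fragment length (resampled up to 20
#'   times, then error).
#' @return list: `nucleotide` (the degraded pseudogene), `protein` (longest
#'   surviving fragment), `n_stops`, `n_indels`.
#' @export
degrade_to_eve <- function(sequence, eve_params, min_len = 50L) {
  stops <- c("TAA", "TAG", "TGA")
  for (attempt in seq_len(20)) {
    nt <- back_translate(sequence)
    n_cod <- nchar(nt) %/% 3
    frac <- runif(1, eve_params$fragment_fraction_range[1],
                  eve_params$fragment_fraction_range[2])
    keep <- max(1L, round(n_cod * frac))
    start <- sample.int(n_cod - keep + 1L, 1)
    nt <- substr(nt, 3 * (start - 1L) + 1L, 3 * (start + keep - 1L))
    ## premature stops, per codon
    hit <- which(runif(keep) < eve_params$stop_rate)
    for (k in hit) {
      substr(nt, 3 * k - 2L, 3 * k) <- sample(stops, 1)
    }
    ## single-nt indels, per site
    chars <- strsplit(nt, "")[[1]]
    idel <- which(runif(length(chars)) < eve_params$frameshift_rate)
    if (length(idel)) {
      for (k in rev(idel)) {
        if (runif(1) < 0.5) {
          chars <- chars[-k]
        } else {
          chars <- append(chars, sample(c("A", "C", "G", "T"), 1), after = k)
        }
      }
    }
    nt_out <- paste0(chars, collapse = "")
    frags <- strsplit(translate_nt(nt_out), "*", fixed = TRUE)[[1]]
    frags <- frags[nzchar(frags)]
    if (length(frags) && max(nchar(frags)) >= min_len) {
      best <- frags[which.max(nchar(frags))]
      return(list(nucleotide = nt_out, protein = best,
                  n_stops = length(hit), n_indels = length(idel)))
    }
  }
  stop("degradation left no fragment of >= ", min_len,
       " aa after 20 attempts")
}

.TITLE_TEMPLATES <- c("hypothetical protein %s", "uncharacterized protein %s",
                      "unknown protein", "unnamed protein product",
                      "DUF%d domain-containing protein",
                      "unclassified protein %s")

.random_title <- function(id, uniref) {
  if (uniref && runif(1) < 0.2) return(sprintf("putative protein %s", id))
  tpl <- sample(.TITLE_TEMPLATES, 1)
  if (grepl("%d", tpl)) sprintf(tpl, sample(1000:4999, 1))
  else if (grepl("%s", tpl)) sprintf(tpl, id) else tpl
}

.random_background_seq <- function(n) {
  paste0(sample(AA20, n, replace = TRUE, prob = ROBINSON_BG), collapse = "")
}

#' Generate a labelled synthetic corpus
#'
#' Produces protein records for five truth classes (intact RdRp, RT,
#' EVE-derived fragment, near-miss decoy, unrelated background), with
#' metadata emulating the screened databases: intact RdRp/RT records carry
#' `assembled_rna` (or occasionally `mrna`) sources with kb-scale contigs;
#' EVE records carry `genomic_dna` sources with Mb-scale contigs; all titles
#' match the unknown-protein search terms. Deterministic in the config.
#'
#' @param config a [corpus_config()].
#' @return list with `records` (corpus tibble incl. sequences), `truth`
#'   (record_id, class, planted_start, planted_end, 0-based half-open) and
#'   `eve_nucleotide` (named character vector of EVE pseudogenes).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  prof <- builtin_profiles()
  cons <- builtin_consensi()
  lm <- config$length_models

  with_rng(config$seed, {
    rows <- list(); truths <- list(); eve_nt <- character(0)
    idx <- 0L
    next_id <- function() {
      idx <<- idx + 1L
      sprintf("SYN%05d", idx)
    }

    embed_domain <- function(domain, total_model) {
      total <- round(.rlnorm_mean(1, total_model))
      dlen <- nchar(domain)
      if (total <= dlen + 2) {
        list(seq = domain, start = 0L, end = dlen)
      } else {
        left <- sample.int(total - dlen + 1L, 1) - 1L
        right <- total - dlen - left
        list(seq = paste0(.random_background_seq(left), domain,
                          .random_background_seq(right)),
             start = left, end = left + dlen)
      }
    }

    rna_meta <- function(id, prot_len) {
      mrna <- runif(1) < 0.1
      if (mrna) {
        clen <- 3 * prot_len + round(.rlnorm_mean(1, c(mean = 800, sdlog = 0.6)))
        type <- "mrna"
      } else {
        clen <- round(.rlnorm_mean(1, lm$assembled_rna))
        type <- "assembled_rna"
      }
      list(molecule_type = type, contig_id = sprintf("contig_%s", id),
           contig_length_nt = clen, is_mitochondrial = FALSE)
    }

    add_record <- function(id, sequence, class, planted, taxon, meta) {
      uniref <- runif(1) < 0.25
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        record_id = id, sequence = sequence,
        title = .random_title(id, uniref),
        source_db = if (uniref) "uniref" else "ncbi",
        taxon_label = taxon,
        molecule_type = meta$molecule_type,
        contig_id = meta$contig_id,
        contig_length_nt = meta$contig_length_nt,
        is_mitochondrial = meta$is_mitochondrial,
        host_lineage = NA_character_
      )
      truths[[length(truths) + 1L]] <<- tibble::tibble(
        record_id = id, class = class,
        planted_start = planted[1], planted_end = planted[2]
      )
    }

    intact_taxa <- c("viruses", "riboviria", "eukaryota", "bacteria",
                     "synthetic_vector", "metagenome")
    intact_probs <- c(0.25, 0.20, 0.41, 0.07, 0.06, 0.01)

    for (i in seq_len(config$n_rdrp_intact)) {
      id <- next_id()
      dom <- sample_from_profile(prof$rdrp)
      emb <- embed_domain(dom, lm$protein_intact)
      add_record(id, emb$seq, "rdrp_intact", c(emb$start, emb$end),
                 sample(intact_taxa, 1, prob = intact_probs),
                 rna_meta(id, nchar(emb$seq)))
    }
    for (i in seq_len(config$n_rt)) {
      id <- next_id()
      dom <- sample_from_profile(prof$rt)
      emb <- embed_domain(dom, lm$protein_rt)
      add_record(id, emb$seq, "rt", c(emb$start, emb$end),
                 sample(c("eukaryota", "bacteria"), 1, prob = c(0.8, 0.2)),
                 rna_meta(id, nchar(emb$seq)))
    }
    for (i in seq_len(config$n_eve)) {
      id <- next_id()
      dom <- sample_from_profile(prof$rdrp)
      emb <- embed_domain(dom, lm$protein_intact)
      deg <- degrade_to_eve(emb$seq, config$eve_params)
      eve_nt[[id]] <- deg$nucleotide
      meta <- list(molecule_type = "genomic_dna",
                   contig_id = sprintf("scaffold_%s", id),
                   contig_length_nt = max(round(.rlnorm_mean(1, lm$genomic_dna)),
                                          3 * nchar(deg$protein)),
                   is_mitochondrial = runif(1) < 0.25)
      add_record(id, deg$protein, "rdrp_eve", c(NA_integer_, NA_integer_),
                 "eukaryota", meta)
    }
    block_names <- c("A", "B", "C")
    for (i in seq_len(config$n_nearmiss)) {
      id <- next_id()
      total <- max(60L, round(.rlnorm_mean(1, lm$protein_other)))
      seqc <- strsplit(.random_background_seq(total), "")[[1]]
      b <- block_names[(i - 1L) %% 3L + 1L]
      pos <- .MOTIF_POS[b]
      block <- cons$rdrp[(pos - 1L):(pos + 6L)]  # 8-mer around the palm block
      at <- sample.int(total - length(block) + 1L, 1)
      seqc[at:(at + length(block) - 1L)] <- block
      add_record(id, paste0(seqc, collapse = ""), "nearmiss",
                 c(at - 1L, at - 1L + length(block)),
                 sample(c("eukaryota", "bacteria", "metagenome"), 1,
                        prob = c(0.5, 0.4, 0.1)),
                 rna_meta(id, total))
    }
    for (i in seq_len(config$n_unrelated)) {
      id <- next_id()
      total <- max(60L, round(.rlnorm_mean(1, lm$protein_other)))
      add_record(id, .random_background_seq(total), "unrelated",
                 c(NA_integer_, NA_integer_),
                 sample(c("eukaryota", "bacteria", "archaea", "metagenome"), 1,
                        prob = c(0.45, 0.4, 0.05, 0.1)),
                 rna_meta(id, total))
    }

    records <- dplyr::bind_rows(rows)
    truth <- dplyr::bind_rows(truths)
    validate_records(records)
    rs_log("generate_corpus: %d records (%d intact RdRp, %d RT, %d EVE, %d near-miss, %d unrelated)",
           nrow(records), config$n_rdrp_intact, config$n_rt, config$n_eve,
           config$n_nearmiss, config$n_unrelated)
    list(records = records, truth = truth, eve_nucleotide = eve_nt,
         config = config)
  })
}

#' Write a generated corpus to disk
#'
#' Writes `corpus.fasta`, `corpus.meta.tsv`, `corpus.truth.tsv`,
#' `corpus.eve.fna` (EVE pseudogenes) and `manifest.json` under `out_dir`.
#'
#' @param corpus output of [generate_corpus()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_corpus <- function(corpus, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(corpus$records, file.path(out_dir, "corpus.fasta"))
  write_metadata(corpus$records, file.path(out_dir, "corpus.meta.tsv"))
  readr::write_tsv(corpus$truth, file.path(out_dir, "corpus.truth.tsv"),
                   na = "NA", progress = FALSE)
  if (length(corpus$eve_nucleotide)) {
    write_fasta(tibble::tibble(record_id = names(corpus$eve_nucleotide),
                               sequence = unname(corpus$eve_nucleotide)),
                file.path(out_dir, "corpus.eve.fna"))
  }
  cfg <- corpus$config
  manifest <- list(seed = cfg$seed,
                   counts = list(rdrp_intact = cfg$n_rdrp_intact, rt = cfg$n_rt,
                                 eve = cfg$n_eve, nearmiss = cfg$n_nearmiss,
                                 unrelated = cfg$n_unrelated),
                   n_records = nrow(corpus$records))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
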