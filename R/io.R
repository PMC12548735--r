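#' Read a FASTA file of protein sequences
#'
#' @param path path to a FASTA file.
#' @param aligned logical; when `FALSE` (the default, for unaligned sequence
#'   files) gap characters (`-` or `.`) in any record are a hard error.
#' @return a tibble with columns `record_id`, `title` (the remainder of the
#'   header line, `""` when absent) and `sequence` (uppercased), in file
#'   order. An empty file yields an empty tibble with a warning.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  stopifnot(file.exists(path))
  empty <- tibble::tibble(record_id = character(), title = character(),
                          sequence = character())
  raw <- readLines(path, warn = FALSE)
  if (!any(startsWith(raw, ">"))) {
    warning("FASTA file '", path, "' contains no records")
    return(empty)
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  titles <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (!aligned && any(grepl("[-.]", seqs))) {
    bad <- ids[grepl("[-.]", seqs)]
    stop("gap characters in unaligned FASTA record(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  tibble::tibble(record_id = unname(ids), title = unname(titles),
                 sequence = unname(seqs))
}

#' Write protein sequences to FASTA
#'
#' Sequences are wrapped at 60 columns. `"X"` is permitted; `"*"` characters
#' are stripped with a warning.
#'
#' @param records a tibble with columns `record_id`, `sequence` and
#'   optionally `title`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("record_id", "sequence") %in% names(records)))
  seqs <- records$sequence
  if (any(grepl("*", seqs, fixed = TRUE))) {
    warning("stripping '*' characters from ",
            sum(grepl("*", seqs, fixed = TRUE)), " sequence(s)")
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  hdr <- records$record_id
  if (!is.null(records[["title"]])) {
    hdr <- ifelse(nzchar(records[["title"]]), paste(hdr, records[["title"]]), hdr)
  }
  set <- Biostrings::BStringSet(setNames(seqs, hdr))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read an aligned FASTA file as a character matrix
#'
#' @param path path to an aligned FASTA file.
#' @return a character matrix (rows = sequences, named by record id,
#'   columns = alignment columns); gaps are `"-"`.
#' @export
read_msa <- function(path) {
  recs <- read_fasta(path, aligned = TRUE)
  if (nrow(recs) == 0) stop("empty alignment file: ", path)
  msa_matrix(setNames(recs$sequence, recs$record_id))
}

## build an MSA matrix from a named character vector of aligned rows
msa_matrix <- function(rows) {
  widths <- nchar(rows)
  if (length(unique(widths)) != 1) {
    stop("ragged alignment: row lengths ", paste(unique(widths), collapse = ", "))
  }
  m <- do.call(rbind, strsplit(gsub("\\.", "-", toupper(rows)), ""))
  rownames(m) <- names(rows)
  m
}

#' Write an MSA matrix to aligned FASTA
#' @param msa character matrix as returned by [read_msa()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  rows <- apply(msa, 1, paste0, collapse = "")
  write_fasta(tibble::tibble(record_id = rownames(msa), sequence = rows), path)
}

.meta_cols <- c("record_id", "title", "source_db", "taxon_label",
                "molecule_type", "contig_id", "contig_length_nt",
                "is_mitochondrial")

#' Read a protein-record metadata table
#'
#' The TSV must carry a header with columns `record_id`, `title`,
#' `source_db`, `taxon_label`, `molecule_type`, `contig_id`,
#' `contig_length_nt`, `is_mitochondrial` (optional extra column
#' `host_lineage`, `;`-separated). `"NA"` cells mean absent; absent
#' `taxon_label`/`molecule_type` map to `"unknown"`.
#'
#' @param path path to the TSV.
#' @return a tibble of record skeletons (no sequences).
#' @export
read_metadata <- function(path) {
  stopifnot(file.exists(path))
  meta <- readr::read_tsv(path, col_types = readr::cols(
    record_id = readr::col_character(),
    title = readr::col_character(),
    source_db = readr::col_character(),
    taxon_label = readr::col_character(),
    molecule_type = readr::col_character(),
    contig_id = readr::col_character(),
    contig_length_nt = readr::col_double(),
    is_mitochondrial = readr::col_logical(),
    .default = readr::col_character()
  ), progress = FALSE)
  missing <- setdiff(.meta_cols, names(meta))
  if (length(missing)) stop("metadata is missing column(s): ",
                            paste(missing, collapse = ", "))
  meta$taxon_label[is.na(meta$taxon_label)] <- "unknown"
  meta$molecule_type[is.na(meta$molecule_type)] <- "unknown"
  meta$is_mitochondrial[is.na(meta$is_mitochondrial)] <- FALSE
  for (col in c("source_db", "taxon_label", "molecule_type")) {
    allowed <- switch(col, source_db = SOURCE_DBS, taxon_label = TAXON_LABELS,
                      molecule_type = MOLECULE_TYPES)
    bad <- which(!is.na(meta[[col]]) & !meta[[col]] %in% allowed)
    if (length(bad)) {
      stop("unknown ", col, " token '", meta[[col]][bad[1]], "' in row ",
           bad[1], " (record ", meta$record_id[bad[1]], ")")
    }
  }
  if (any(is.na(meta$source_db))) {
    stop("source_db absent in row ", which(is.na(meta$source_db))[1])
  }
  if (is.null(meta[["host_lineage"]])) meta$host_lineage <- NA_character_
  meta
}

#' Write a protein-record metadata table
#' @param meta metadata tibble (see [read_metadata()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  cols <- intersect(c(.meta_cols, "host_lineage"), names(meta))
  readr::write_tsv(meta[, cols], path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read and join a sequence corpus (FASTA + metadata TSV)
#'
#' @param fasta_path FASTA of protein sequences.
#' @param meta_path metadata TSV keyed by `record_id`.
#' @return a validated tibble of protein records, one per FASTA entry, with
#'   sequence and metadata columns.
#' @export
read_corpus <- function(fasta_path, meta_path) {
  seqs <- read_fasta(fasta_path)
  meta <- read_metadata(meta_path)
  orphan <- setdiff(meta$record_id, seqs$record_id)
  if (length(orphan)) {
    stop("record_id present in metadata but not FASTA: ",
         paste(head(orphan, 5), collapse = ", "))
  }
  records <- dplyr::left_join(seqs[, c("record_id", "sequence")], meta,
                              by = "record_id")
  validate_records(records)
  records
}

#' Validate protein-record invariants
#'
#' Checks the record contract: non-empty uppercase sequences over the
#' 20-letter alphabet plus `X`; unique ids; and, for `genomic_dna`/`mrna`
#' records carrying a contig length, `contig_length_nt >= 3 *` protein
#' length (a protein cannot outsize its own coding capacity).
#'
#' @param records a corpus tibble.
#' @return `records`, invisibly; errors on the first violated invariant.
#' @export
validate_records <- function(records) {
  if (anyDuplicated(records$record_id)) {
    stop("duplicate record_id: ",
         records$record_id[duplicated(records$record_id)][1])
  }
  if (any(!nzchar(records$sequence))) stop("empty sequence present")
  pat <- paste0("^[", paste(AA20, collapse = ""), "X]+$")
  bad <- !grepl(pat, records$sequence)
  if (any(bad)) {
    stop("sequence with invalid characters: ", records$record_id[bad][1])
  }
  if (!is.null(records$contig_length_nt)) {
    coding <- records$molecule_type %in% c("genomic_dna", "mrna") &
      !is.na(records$contig_length_nt)
    short <- coding & records$contig_length_nt < 3 * nchar(records$sequence)
    if (any(short)) {
      stop("contig_length_nt < 3 x protein length for record ",
           records$record_id[short][1])
    }
  }
  invisible(records)
}

#' Select records with "unknown protein" style titles
#'
#' Case-insensitive substring match on the six unknown-protein search terms
#' (uncharacterized, unclassified, unknown, unnamed, hypothetical, DUF);
#' records with `source_db == "uniref"` additionally match "putative".
#' A pure, idempotent filter: output is a subset of input, order preserved.
#'
#' @param records tibble with `title` (and optionally `source_db`) columns.
#' @return the selected subset.
#' @export
select_uncharacterized <- function(records) {
  stopifnot("title" %in% names(records))
  titles <- tolower(records$title)
  hit <- Reduce(`|`, lapply(UNKNOWN_TERMS, function(t) {
    grepl(t, titles, fixed = TRUE)
  }))
  if (!is.null(records$source_db)) {
    hit <- hit | (records$source_db == "uniref" &
                    grepl("putative", titles, fixed = TRUE))
  }
  out <- records[hit, , drop = FALSE]
  rs_log_funnel("select_uncharacterized", nrow(records), nrow(out))
  out
}
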