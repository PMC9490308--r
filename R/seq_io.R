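# Reading and writing marker panels: one FASTA per marker + a taxonomy TSV.
# FASTA record id = accession_id (text after the first whitespace is ignored).

TAXONOMY_COLS <- c("accession_id", "genus", "species", "infrataxon", "infrataxon_rank")

read_taxonomy <- function(path) {
  if (!file.exists(path)) {
    stop_validation("taxonomy file not found: '%s'", path)
  }
  tax <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(TAXONOMY_COLS, names(tax))
  if (length(missing_cols) > 0) {
    stop_validation("taxonomy file '%s' lacks column(s): %s", path,
                    paste(missing_cols, collapse = ", "))
  }
  tax
}

read_marker_fasta <- function(path, marker_id) {
  if (!file.exists(path)) {
    stop_validation("FASTA for marker '%s' not found: '%s'", marker_id, path)
  }
  # BStringSet: tolerant of U / lowercase; sanitized and validated downstream.
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop_validation("duplicate record id '%s' in FASTA of marker '%s' ('%s')",
                    ids[duplicated(ids)][1], marker_id, path)
  }
  seqs <- as.character(set)
  names(seqs) <- ids
  # report bad characters with file / record / position before panel assembly
  clean <- sanitize_sequence(seqs)
  bad <- first_bad_char(clean)
  if (any(bad > 0)) {
    k <- which(bad > 0)[1]
    stop_validation("non-IUPAC character at position %d in record '%s' of '%s' (marker '%s')",
                    bad[k], ids[k], path, marker_id)
  }
  seqs
}

#' Read a marker panel from FASTA files and a taxonomy table
#'
#' @param fasta_paths Named character vector or list mapping marker id to a
#'   FASTA path; the order of the names fixes the marker order of the
#'   composite code (H1, H2, ...). Each FASTA must contain exactly one record
#'   per accession listed in the taxonomy table, keyed by `accession_id`.
#' @param taxonomy_path Path to a tab-separated taxonomy table with columns
#'   `accession_id`, `genus`, `species`, `infrataxon`, `infrataxon_rank`.
#'   Its row order fixes the panel's accession order.
#' @return A [marker_panel()].
#' @export
read_panel <- function(fasta_paths, taxonomy_path) {
  fasta_paths <- unlist(fasta_paths)
  if (is.null(names(fasta_paths)) || any(!nzchar(names(fasta_paths)))) {
    stop_validation("fasta_paths must be named by marker id")
  }
  tax <- read_taxonomy(taxonomy_path)
  seq_tbl <- purrr::imap(fasta_paths, function(path, marker) {
    seqs <- read_marker_fasta(path, marker)
    absent <- setdiff(tax$accession_id, names(seqs))
    if (length(absent) > 0) {
      stop_validation("accession '%s' listed in taxonomy but absent from FASTA of marker '%s'",
                      absent[1], marker)
    }
    extra <- setdiff(names(seqs), tax$accession_id)
    if (length(extra) > 0) {
      stop_validation("FASTA of marker '%s' contains record '%s' not listed in taxonomy",
                      marker, extra[1])
    }
    tibble::tibble(accession_id = names(seqs), marker_id = marker,
                   sequence = unname(seqs))
  })
  marker_panel(tax, names(fasta_paths), dplyr::bind_rows(seq_tbl))
}

#' Write a marker panel to disk
#'
#' Writes one FASTA per marker (`<marker>.fasta`) plus `taxonomy.tsv` into
#' `out_dir`. `read_panel()` on the written files reproduces the panel
#' exactly.
#'
#' @param panel A `marker_panel` with at least one accession.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of written paths
#'   (markers plus `"taxonomy"`).
#' @export
write_panel <- function(panel, out_dir) {
  if (!inherits(panel, "marker_panel")) {
    stop_validation("write_panel() expects a marker_panel")
  }
  if (nrow(panel$accessions) == 0) {
    stop_validation("refusing to write an empty panel (0 accessions)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (mk in panel$markers$marker_id) {
    seqs <- panel_sequences(panel, mk)
    path <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9._-]", "_", mk), ".fasta"))
    set <- Biostrings::BStringSet(seqs)
    Biostrings::writeXStringSet(set, path, width = 70)
    paths[mk] <- path
  }
  tax_path <- file.path(out_dir, "taxonomy.tsv")
  readr::write_tsv(panel$accessions, tax_path, na = "")
  paths["taxonomy"] <- tax_path
  invisible(paths)
}
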