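#' Assemble an accession-by-marker sequence panel
#'
#' A marker panel is the central input of the barcoding pipeline: a set of
#' accessions (germplasm entries with genus / species / optional variety or
#' cultivar identity), an ordered set of markers, and one DNA sequence per
#' accession and marker. Sequences may carry alignment gaps (`-`); when all
#' sequences of a marker share the same string length the marker is treated
#' as aligned downstream.
#'
#' @param accessions Data frame with columns `accession_id`, `genus`,
#'   `species`, `infrataxon` (NA when absent) and `infrataxon_rank`
#'   (`"none"`, `"variety"` or `"cultivar"`). Row order fixes the panel's
#'   canonical accession order, which in turn fixes haplotype letter order.
#' @param markers Character vector of marker ids in composite-code order
#'   (position in this vector is the marker index used in labels H1, H2, ...),
#'   or a data frame with columns `marker_id` and `marker_index`.
#' @param sequences Data frame with columns `accession_id`, `marker_id`,
#'   `sequence`. Every accession/marker pair must be present exactly once.
#'   Sequences are uppercased and `U` is mapped to `T`; any character outside
#'   the IUPAC nucleotide codes plus `-` is rejected with its position.
#'
#' @return An object of class `marker_panel`: a list with tibbles
#'   `accessions`, `markers` and `sequences`.
#' @examples
#' p <- marker_panel(
#'   accessions = tibble::tibble(
#'     accession_id = "X1", genus = "Lolium", species = "perenne",
#'     infrataxon = NA_character_, infrataxon_rank = "none"
#'   ),
#'   markers = "rbcL",
#'   sequences = tibble::tibble(
#'     accession_id = "X1", marker_id = "rbcL", sequence = "acgt"
#'   )
#' )
#' p$sequences$sequence # "ACGT"
#' @export
marker_panel <- function(accessions, markers, sequences) {
  accessions <- tibble::as_tibble(accessions)
  need <- c("accession_id", "genus", "species", "infrataxon", "infrataxon_rank")
  missing_cols <- setdiff(need, names(accessions))
  if (length(missing_cols) > 0) {
    stop_validation("taxonomy table lacks column(s): %s",
                    paste(missing_cols, collapse = ", "))
  }
  accessions <- accessions[need]
  accessions$infrataxon <- as.character(accessions$infrataxon)
  accessions$infrataxon[!is.na(accessions$infrataxon) &
                          accessions$infrataxon == ""] <- NA_character_

  if (anyDuplicated(accessions$accession_id)) {
    dup <- accessions$accession_id[duplicated(accessions$accession_id)][1]
    stop_validation("duplicate accession_id in taxonomy: '%s'", dup)
  }
  bad_rank <- !accessions$infrataxon_rank %in% c("none", "variety", "cultivar")
  if (any(bad_rank)) {
    stop_validation("invalid infrataxon_rank '%s' for accession '%s'",
                    accessions$infrataxon_rank[bad_rank][1],
                    accessions$accession_id[bad_rank][1])
  }
  mismatch <- xor(is.na(accessions$infrataxon),
                  accessions$infrataxon_rank == "none")
  if (any(mismatch)) {
    stop_validation(
      "accession '%s': infrataxon and infrataxon_rank disagree (rank must be 'none' iff infrataxon is absent)",
      accessions$accession_id[mismatch][1])
  }

  if (is.data.frame(markers)) {
    markers <- tibble::as_tibble(markers)
    if (!all(c("marker_id", "marker_index") %in% names(markers))) {
      stop_validation("marker table needs columns marker_id and marker_index")
    }
    markers <- markers[order(markers$marker_index), c("marker_id", "marker_index")]
    if (!identical(as.integer(markers$marker_index), seq_len(nrow(markers)))) {
      stop_validation("marker_index values must be 1..M with no gaps or repeats")
    }
  } else {
    markers <- tibble::tibble(marker_id = as.character(markers),
                              marker_index = seq_along(markers))
  }
  if (anyDuplicated(markers$marker_id)) {
    stop_validation("duplicate marker_id: '%s'",
                    markers$marker_id[duplicated(markers$marker_id)][1])
  }

  sequences <- tibble::as_tibble(sequences)
  if (!all(c("accession_id", "marker_id", "sequence") %in% names(sequences))) {
    stop_validation("sequence table needs columns accession_id, marker_id, sequence")
  }
  sequences <- sequences[c("accession_id", "marker_id", "sequence")]
  unknown_acc <- setdiff(sequences$accession_id, accessions$accession_id)
  if (length(unknown_acc) > 0) {
    stop_validation("sequence table names accession '%s' absent from taxonomy",
                    unknown_acc[1])
  }
  unknown_mk <- setdiff(sequences$marker_id, markers$marker_id)
  if (length(unknown_mk) > 0) {
    stop_validation("sequence table names marker '%s' absent from marker list",
                    unknown_mk[1])
  }
  key <- paste(sequences$accession_id, sequences$marker_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- strsplit(key[duplicated(key)][1], "\r", fixed = TRUE)[[1]]
    stop_validation("duplicate sequence for accession '%s', marker '%s'", d[1], d[2])
  }
  want <- expand.grid(accession_id = accessions$accession_id,
                      marker_id = markers$marker_id,
                      stringsAsFactors = FALSE)
  want_key <- paste(want$accession_id, want$marker_id, sep = "\r")
  absent <- !want_key %in% key
  if (any(absent)) {
    stop_validation("missing sequence for accession '%s', marker '%s'",
                    want$accession_id[absent][1], want$marker_id[absent][1])
  }

  sequences$sequence <- sanitize_sequence(sequences$sequence)
  bad <- first_bad_char(sequences$sequence)
  if (any(bad > 0)) {
    k <- which(bad > 0)[1]
    stop_validation(
      "non-IUPAC character at position %d in sequence of accession '%s', marker '%s'",
      bad[k], sequences$accession_id[k], sequences$marker_id[k])
  }

  # canonical ordering: taxonomy row order, then marker index
  sequences <- dplyr::arrange(
    sequences,
    match(.data$accession_id, accessions$accession_id),
    match(.data$marker_id, markers$marker_id)
  )

  structure(
    list(accessions = accessions, markers = markers, sequences = sequences),
    class = "marker_panel"
  )
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> %d accessions x %d markers (%d sequences)\n",
              nrow(x$accessions), nrow(x$markers), nrow(x$sequences)))
  cat("markers:", paste(x$markers$marker_id, collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.marker_panel <- function(x, ...) {
  sprintf("<marker_panel> %d accessions x %d markers",
          nrow(x$accessions), nrow(x$markers))
}

# All sequences of one marker, named by accession, in panel order.
panel_sequences <- function(panel, marker_id) {
  if (!marker_id %in% panel$markers$marker_id) {
    stop_validation("unknown marker '%s'", marker_id)
  }
  s <- panel$sequences[panel$sequences$marker_id == marker_id, ]
  stats::setNames(s$sequence, s$accession_id)
}

#' Group accessions into taxonomic evaluation units
#'
#' Discrimination statistics are computed over disjoint groups of accessions
#' treated as one terminal taxon. Levels:
#' * `"taxon"` — species or named variety; conspecific cultivars collapse
#'   into one unit (the level at which the combined code is scored);
#' * `"species"` — genus + species, varieties and cultivars both collapse;
#' * `"genus"` — one unit per genus;
#' * `"accession"` — every accession its own unit.
#'
#' @param panel A `marker_panel`.
#' @param level One of `"taxon"`, `"species"`, `"genus"`, `"accession"`.
#' @return Named list of character vectors of accession ids.
#' @export
taxon_units <- function(panel, level = c("taxon", "species", "genus", "accession")) {
  level <- match.arg(level)
  a <- panel$accessions
  key <- switch(
    level,
    accession = a$accession_id,
    genus = a$genus,
    species = paste(a$genus, a$species),
    taxon = ifelse(a$infrataxon_rank == "variety",
                   paste(a$genus, a$species, "var.", a$infrataxon),
                   paste(a$genus, a$species))
  )
  split(a$accession_id, factor(key, levels = unique(key)))
}

#' Extract a marker's sequences as an aligned block
#'
#' Returns the equal-length (gapped) sequences of one marker as an
#' `aligned_block`, the input of the distance and tree stages. If the stored
#' sequences differ in length, `pad = TRUE` pads them with terminal gaps to
#' the longest sequence (no alignment is attempted); `pad = FALSE` raises an
#' error instead.
#'
#' @param panel A `marker_panel`.
#' @param marker_id Marker to extract.
#' @param pad Pad unequal-length sequences with terminal gaps.
#' @return An `aligned_block` (named character vector with equal widths).
#' @export
panel_alignment <- function(panel, marker_id, pad = TRUE) {
  seqs <- panel_sequences(panel, marker_id)
  w <- nchar(seqs)
  if (length(unique(w)) > 1) {
    if (!pad) {
      stop_validation("marker '%s' sequences have unequal lengths and pad = FALSE",
                      marker_id)
    }
    seqs <- paste0(seqs, strrep("-", max(w) - w))
    names(seqs) <- names(w)
  }
  aligned_block(seqs)
}

#' Construct an aligned block
#'
#' @param sequences Named character vector (names are accession ids) of
#'   equal-length gapped sequences.
#' @return Object of class `aligned_block`.
#' @export
aligned_block <- function(sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop_validation("aligned block sequences must be named by accession")
  }
  if (anyDuplicated(names(sequences))) {
    stop_validation("duplicate accession '%s' in aligned block",
                    names(sequences)[duplicated(names(sequences))][1])
  }
  sequences <- sanitize_sequence(sequences)
  w <- unique(nchar(sequences))
  if (length(w) != 1) {
    stop_validation("aligned block sequences must have equal length")
  }
  bad <- first_bad_char(sequences)
  if (any(bad > 0)) {
    k <- which(bad > 0)[1]
    stop_validation("non-IUPAC character at position %d in sequence '%s'",
                    bad[k], names(sequences)[k])
  }
  structure(sequences, class = "aligned_block", width = w)
}

#' @export
print.aligned_block <- function(x, ...) {
  cat(sprintf("<aligned_block> %d sequences x %d positions\n",
              length(x), attr(x, "width")))
  invisible(x)
}
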