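# Haplotype collapsing: partition a marker's sequences into identity classes
# and label them H<marker_index>^<letter> in order of first appearance.

# Identity keys for a set of marker sequences. For aligned input (all stored
# strings of equal length) alignment columns holding a gap in ANY sequence are
# excluded before comparison, so accessions that differ only by an indel share
# a haplotype while their ungapped lengths still differ -- the convention of
# standard haplotype software when gaps are not counted as differences, and a
# transitive relation. Unaligned input (unequal stored lengths) falls back to
# exact equality of the ungapped strings.
haplotype_keys <- function(seqs) {
  w <- nchar(seqs)
  if (length(seqs) > 1 && length(unique(w)) == 1 && any(grepl("-", seqs, fixed = TRUE))) {
    mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seqs), byrow = TRUE)
    keep <- colSums(mat == "-") == 0
    apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  } else {
    strip_gaps(seqs)
  }
}

#' Collapse one marker's sequences into haplotype classes
#'
#' Partitions the panel's accessions into classes of identical sequences at
#' `marker_id` and assigns canonical labels `H<k>^<letter>` (k = the marker's
#' position in the composite code; letters A, B, C, ... in order of first
#' appearance under the panel's accession order). Two accessions share a
#' class iff their uppercased sequences are equal after gap handling: for
#' aligned markers, columns with a gap in any sequence are ignored (so
#' indel-only differences do not split a class); otherwise the ungapped
#' strings must be equal character-for-character.
#'
#' @param panel A [marker_panel()].
#' @param marker_id Marker to collapse.
#' @return Object of class `haplotype_assignment`: list with `marker_id`,
#'   `marker_index`, `classes` (tibble: `label`, `letter`, `length_bp` of the
#'   representative, `representative`, `n_members`, `members` list-column) and
#'   `membership` (tibble: `accession_id`, `label`, `letter`, `length_bp` of
#'   each accession's own ungapped sequence).
#' @examples
#' p <- marker_panel(
#'   accessions = tibble::tibble(
#'     accession_id = c("a", "b"), genus = "G", species = c("x", "y"),
#'     infrataxon = NA_character_, infrataxon_rank = "none"
#'   ),
#'   markers = "m",
#'   sequences = tibble::tibble(
#'     accession_id = c("a", "b"), marker_id = "m",
#'     sequence = c("ACGT", "ACGA")
#'   )
#' )
#' collapse_haplotypes(p, "m")$classes$label # "H1^A" "H1^B"
#' @export
collapse_haplotypes <- function(panel, marker_id) {
  if (!inherits(panel, "marker_panel")) {
    stop_validation("collapse_haplotypes() expects a marker_panel")
  }
  k <- panel$markers$marker_index[match(marker_id, panel$markers$marker_id)]
  if (is.na(k)) stop_validation("unknown marker '%s'", marker_id)
  seqs <- panel_sequences(panel, marker_id)
  if (length(seqs) == 0) {
    stop_validation("no sequences for marker '%s'", marker_id)
  }
  keys <- haplotype_keys(seqs)
  cls <- match(keys, unique(keys))          # class index by first appearance
  letters_ <- class_letters(max(cls))
  labels <- haplotype_label(k, letters_[cls])

  membership <- tibble::tibble(
    accession_id = names(seqs),
    label = labels,
    letter = letters_[cls],
    length_bp = ungapped_length(seqs)
  )
  first <- !duplicated(cls)
  classes <- tibble::tibble(
    label = labels[first],
    letter = letters_[cls][first],
    length_bp = ungapped_length(seqs[first]),
    representative = unname(seqs[first]),
    n_members = as.integer(table(cls)[as.character(cls[first])]),
    members = unname(split(names(seqs), cls))[order(unique(cls))]
  )

  structure(
    list(marker_id = marker_id, marker_index = k,
         classes = classes, membership = membership),
    class = "haplotype_assignment"
  )
}

#' @export
print.haplotype_assignment <- function(x, ...) {
  cat(sprintf("<haplotype_assignment> marker %s (H%d): %d accessions in %d classes\n",
              x$marker_id, x$marker_index, nrow(x$membership), nrow(x$classes)))
  print(x$classes[c("label", "length_bp", "n_members")])
  invisible(x)
}

#' Count haplotype classes within a subset of accessions
#'
#' @param assignment A [collapse_haplotypes()] result.
#' @param accession_subset Non-empty character vector of accession ids
#'   (must all be present in the assignment).
#' @return Integer: number of distinct classes intersecting the subset.
#' @export
count_haplotypes <- function(assignment, accession_subset) {
  if (!inherits(assignment, "haplotype_assignment")) {
    stop_validation("count_haplotypes() expects a haplotype_assignment")
  }
  accession_subset <- unique(as.character(accession_subset))
  if (length(accession_subset) == 0) {
    stop_validation("accession subset is empty")
  }
  unknown <- setdiff(accession_subset, assignment$membership$accession_id)
  if (length(unknown) > 0) {
    stop_validation("accession '%s' not in haplotype assignment of marker '%s'",
                    unknown[1], assignment$marker_id)
  }
  m <- assignment$membership
  dplyr::n_distinct(m$label[m$accession_id %in% accession_subset])
}

#' Collapse every marker of a panel
#'
#' @param panel A [marker_panel()].
#' @return Named list of `haplotype_assignment` objects, one per marker, in
#'   composite-code order.
#' @export
collapse_all <- function(panel) {
  mk <- panel$markers$marker_id
  setNames(lapply(mk, function(m) collapse_haplotypes(panel, m)), mk)
}

#' Tabulate haplotype assignments
#'
#' One row per haplotype class across markers, mirroring the `Haplotype`
#' columns of a barcode database table.
#'
#' @param assignments A single `haplotype_assignment` or a list of them.
#' @return Tibble with `marker_id`, `label`, `length_bp`, `n_members`,
#'   `members` (comma-separated accession ids).
#' @export
haplotype_table <- function(assignments) {
  if (inherits(assignments, "haplotype_assignment")) assignments <- list(assignments)
  purrr::map_dfr(assignments, function(a) {
    tibble::tibble(
      marker_id = a$marker_id,
      label = a$classes$label,
      length_bp = a$classes$length_bp,
      n_members = a$classes$n_members,
      members = purrr::map_chr(a$classes$members, paste, collapse = ",")
    )
  })
}

#' Write representative haplotype sequences to FASTA
#'
#' @param assignment A `haplotype_assignment`.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_representatives <- function(assignment, path) {
  set <- Biostrings::BStringSet(setNames(assignment$classes$representative,
                                         assignment$classes$label))
  Biostrings::writeXStringSet(set, path, width = 70)
  invisible(path)
}
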