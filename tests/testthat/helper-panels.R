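# In-code fixtures shared across tests.

# Build a panel from a list: marker_id -> named character vector of sequences.
tiny_panel <- function(seqs_by_marker, genus = NULL, species = NULL) {
  ids <- names(seqs_by_marker[[1]])
  if (is.null(genus)) genus <- rep("Genus", length(ids))
  if (is.null(species)) species <- paste0("sp", seq_along(ids))
  marker_panel(
    accessions = tibble::tibble(
      accession_id = ids, genus = genus, species = species,
      infrataxon = NA_character_, infrataxon_rank = "none"
    ),
    markers = names(seqs_by_marker),
    sequences = purrr::imap_dfr(seqs_by_marker, function(seqs, mk) {
      tibble::tibble(accession_id = names(seqs), marker_id = mk,
                     sequence = unname(seqs))
    })
  )
}

# A random gap-free panel with forced haplotype collisions: k distinct base
# sequences per marker, assigned randomly to n accessions.
random_panel <- function(n = 8, markers = c("m1", "m2"), len = 30, k = 3) {
  seqs_by_marker <- lapply(setNames(markers, markers), function(mk) {
    pool <- replicate(k, paste(sample(c("A", "C", "G", "T"), len, TRUE),
                               collapse = ""))
    setNames(sample(pool, n, replace = TRUE), paste0("acc", seq_len(n)))
  })
  tiny_panel(seqs_by_marker)
}

# Brute-force haplotype partition by all-pairs exact string comparison
# (independent of the package's collapsing path; gap-free input).
brute_partition <- function(seqs) {
  n <- length(seqs)
  cls <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    hit <- 0L
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        if (identical(seqs[[i]], seqs[[j]])) { hit <- cls[j]; break }
      }
    }
    if (hit == 0L) { nxt <- nxt + 1L; hit <- nxt }
    cls[i] <- hit
  }
  cls
}

# Canonicalize a partition (vector of class ids) for comparisons.
canon_partition <- function(cls) match(cls, unique(cls))

eight_species_ids <- c("AGC_CRI", "BRI", "ELD", "ELS", "ETR", "FER", "LEC",
                       "LOP_MED")
agropyron_ids <- c("AGC_CRI", "AGC_PEC", "AGM", "AGD")
lolium_ids <- c("LOP_MED", "LOP_PIC", "LOP_TAY", "LOP_ASC")
grass_markers <- c("ITS", "matK", "rbcL", "trnL-F")

fixture_panel <- function(seed = 1) generate_fixture(seed = seed)
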