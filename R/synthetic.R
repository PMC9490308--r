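# Synthetic sequence panels: a deterministic fixture realizing the published
# grass panel's length and haplotype-equality structure, and a hierarchical
# divergence simulator (genus -> species -> accession) with a known genealogy.

#' Specification of the 14-accession grass fixture panel
#'
#' Reads the packaged, human-readable transcription of the published grass
#' barcode database: 14 accessions across 7 genera, 4 markers (ITS, matK,
#' rbcL, trnL-F), per-accession sequence lengths and the haplotype classes
#' implied by the printed labels (e.g. rbcL groups all four Agropyron
#' accessions; the four Lolium perenne cultivars are identical at every
#' marker).
#'
#' @param accessions_path,haplotypes_path Paths to the TSV transcriptions;
#'   the packaged files by default.
#' @return Object of class `fixture_spec`: list with tibbles `accessions`
#'   and `haplotypes` (accession_id, marker_id, length_bp, class_letter) and
#'   the marker order `markers`.
#' @export
grass_fixture_spec <- function(
    accessions_path = system.file("extdata", "grass_accessions.tsv",
                                  package = "haplocode"),
    haplotypes_path = system.file("extdata", "grass_haplotypes.tsv",
                                  package = "haplocode")) {
  accessions <- readr::read_tsv(
    accessions_path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE)
  haplotypes <- readr::read_tsv(
    haplotypes_path,
    col_types = readr::cols(accession_id = readr::col_character(),
                            marker_id = readr::col_character(),
                            length_bp = readr::col_integer(),
                            class_letter = readr::col_character()),
    progress = FALSE)
  markers <- unique(haplotypes$marker_id)
  spec <- structure(
    list(accessions = accessions, haplotypes = haplotypes, markers = markers),
    class = "fixture_spec")
  validate_fixture_spec(spec)
  spec
}

validate_fixture_spec <- function(spec) {
  acc <- spec$accessions
  hap <- spec$haplotypes
  if (anyDuplicated(acc$accession_id)) {
    stop_validation("fixture spec: duplicate accession_id")
  }
  want <- expand.grid(accession_id = acc$accession_id, marker_id = spec$markers,
                      stringsAsFactors = FALSE)
  key <- paste(hap$accession_id, hap$marker_id)
  if (anyDuplicated(key)) {
    stop_validation("fixture spec: duplicate (accession, marker) row")
  }
  absent <- setdiff(paste(want$accession_id, want$marker_id), key)
  if (length(absent) > 0) {
    stop_validation("fixture spec: missing cell '%s'", absent[1])
  }
  extra <- setdiff(hap$accession_id, acc$accession_id)
  if (length(extra) > 0) {
    stop_validation("fixture spec: haplotype row for unknown accession '%s'", extra[1])
  }
  # letters must form A, B, C, ... in order of first appearance per marker
  for (m in spec$markers) {
    sub <- hap[hap$marker_id == m, ]
    sub <- sub[match(acc$accession_id, sub$accession_id), ]
    lv <- unique(sub$class_letter)
    if (!identical(lv, class_letters(length(lv)))) {
      stop_validation("fixture spec: marker '%s' letters are not canonical (A, B, ... by first appearance)", m)
    }
  }
  invisible(spec)
}

#' Generate the deterministic grass fixture panel
#'
#' Emits a 14 x 4 [marker_panel()] whose sequences realize the fixture
#' specification exactly: each sequence's ungapped length equals the printed
#' length, two accessions are identical at a marker iff their printed
#' haplotype labels coincide, and distinct classes differ by at least
#' `min_class_divergence` substitutions at gap-free alignment columns.
#' Per marker, sequences are stored aligned: a seeded random base sequence of
#' the marker's maximum length, class-specific substitutions at dedicated
#' columns within the shared (gap-free) prefix, and terminal gaps padding
#' shorter accessions. The real study sequences are unpublished; only this
#' length/partition structure is reproducible.
#'
#' @param spec A [grass_fixture_spec()] (or a compatible `fixture_spec`).
#' @param seed Integer seed; a fixed seed gives byte-identical panels.
#' @param min_class_divergence Minimum number of substitutions separating any
#'   two haplotype classes of a marker (>= 1).
#' @return A `marker_panel` whose per-marker sequences are equal-length
#'   (aligned) gapped strings; [panel_alignment()] extracts them as blocks.
#' @export
generate_fixture <- function(spec = grass_fixture_spec(), seed = 1,
                             min_class_divergence = 1) {
  if (!inherits(spec, "fixture_spec")) {
    stop_validation("generate_fixture() expects a fixture_spec")
  }
  validate_fixture_spec(spec)
  if (min_class_divergence < 1) {
    stop_validation("min_class_divergence must be >= 1")
  }
  m <- as.integer(min_class_divergence)
  set.seed(seed)
  acc_ids <- spec$accessions$accession_id
  bases <- c("A", "C", "G", "T")

  rows <- list()
  for (mk in spec$markers) {
    sub <- spec$haplotypes[spec$haplotypes$marker_id == mk, ]
    sub <- sub[match(acc_ids, sub$accession_id), ]
    aln_len <- max(sub$length_bp)
    safe_len <- min(sub$length_bp)
    letters_ <- unique(sub$class_letter)
    k <- length(letters_)
    if (k * m > safe_len) {
      stop_validation("marker '%s': %d classes x divergence %d exceed the %d shared columns",
                      mk, k, m, safe_len)
    }
    base <- sample(bases, aln_len, replace = TRUE)
    pos <- sample.int(safe_len, k * m)
    reps <- lapply(seq_len(k), function(ci) {
      s <- base
      p <- pos[((ci - 1) * m + 1):(ci * m)]
      # deterministic substitution: cycle to the next base
      s[p] <- bases[match(s[p], bases) %% 4 + 1]
      s
    })
    names(reps) <- letters_
    seqs <- vapply(seq_len(nrow(sub)), function(i) {
      len <- sub$length_bp[i]
      paste0(paste(reps[[sub$class_letter[i]]][seq_len(len)], collapse = ""),
             strrep("-", aln_len - len))
    }, character(1))
    rows[[mk]] <- tibble::tibble(accession_id = acc_ids, marker_id = mk,
                                 sequence = seqs)
  }
  marker_panel(spec$accessions, spec$markers, dplyr::bind_rows(rows))
}

#' Specification for the hierarchical panel simulator
#'
#' Defaults emulate the structure of a grass germplasm study: several genera,
#' a few species per genus, conspecific accessions (cultivars) that have not
#' diverged at the barcode markers, marker lengths close to the four standard
#' plant barcodes, and strong genus-level relative to species-level
#' divergence.
#'
#' @param n_genera,species_per_genus,accessions_per_species Panel dimensions
#'   (all >= 1).
#' @param marker_lengths Named integer vector of per-marker sequence lengths.
#' @param rate_genus,rate_species,rate_accession Per-site substitution
#'   probabilities on the branches leading to genus, species and accession
#'   nodes (all >= 0).
#' @param tstv Transition/transversion ratio (> 0); each substitution is a
#'   transition with probability `tstv / (tstv + 1)`.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genera = 7, species_per_genus = 2,
                            accessions_per_species = 2,
                            marker_lengths = c(ITS = 700, matK = 400,
                                               rbcL = 572, `trnL-F` = 460),
                            rate_genus = 0.05, rate_species = 0.01,
                            rate_accession = 0, tstv = 2) {
  if (any(c(n_genera, species_per_genus, accessions_per_species) < 1)) {
    stop_validation("panel dimensions must all be >= 1")
  }
  if (any(c(rate_genus, rate_species, rate_accession) < 0)) {
    stop_validation("substitution rates must be >= 0")
  }
  if (tstv <= 0) stop_validation("tstv must be > 0")
  if (is.null(names(marker_lengths)) || any(!nzchar(names(marker_lengths)))) {
    stop_validation("marker_lengths must be named by marker id")
  }
  structure(
    list(n_genera = as.integer(n_genera),
         species_per_genus = as.integer(species_per_genus),
         accessions_per_species = as.integer(accessions_per_species),
         marker_lengths = marker_lengths,
         rate_genus = rate_genus, rate_species = rate_species,
         rate_accession = rate_accession, tstv = tstv),
    class = "simulation_spec")
}

# one round of substitutions on an integer-encoded sequence (1..4)
mutate_encoded <- function(seq_int, rate, tstv) {
  if (rate <= 0) return(seq_int)
  hit <- which(stats::runif(length(seq_int)) < rate)
  if (length(hit) == 0) return(seq_int)
  is_ts <- stats::runif(length(hit)) < tstv / (tstv + 1)
  cur <- seq_int[hit]
  # coding A=1, G=2, C=3, T=4: transition partner swaps within purine /
  # pyrimidine pairs; transversion picks one of the two cross-class bases.
  ts_partner <- c(2L, 1L, 4L, 3L)
  tv1 <- c(3L, 3L, 1L, 1L)
  tv2 <- c(4L, 4L, 2L, 2L)
  pick2 <- stats::runif(length(hit)) < 0.5
  new <- ifelse(is_ts, ts_partner[cur], ifelse(pick2, tv1[cur], tv2[cur]))
  seq_int[hit] <- new
  seq_int
}

#' Simulate a hierarchical marker panel with known genealogy
#'
#' Draws a uniform random root sequence per marker, then places substitutions
#' independently down the genus -> species -> accession hierarchy with the
#' per-level rates and transition/transversion ratio of `spec`. Returns the
#' panel together with the true genealogy so that tree-recovery and
#' discrimination-power experiments can score against the truth.
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed (required; fixed seed gives identical panels).
#' @return List with `panel` (a [marker_panel()]; accessions named
#'   `G<g>_S<s>_A<a>`) and `genealogy` (a `phylo` whose branch lengths are
#'   the per-level substitution rates).
#' @export
simulate_panel <- function(spec = simulation_spec(), seed) {
  if (!inherits(spec, "simulation_spec")) {
    stop_validation("simulate_panel() expects a simulation_spec")
  }
  if (missing(seed) || is.null(seed)) {
    stop_validation("a seed is required for simulation")
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ng <- spec$n_genera; ns <- spec$species_per_genus; na <- spec$accessions_per_species

  acc <- expand.grid(a = seq_len(na), s = seq_len(ns), g = seq_len(ng))
  acc <- acc[order(acc$g, acc$s, acc$a), ]
  ids <- sprintf("G%d_S%d_A%d", acc$g, acc$s, acc$a)
  accessions <- tibble::tibble(
    accession_id = ids,
    genus = sprintf("Genus%d", acc$g),
    species = sprintf("species%d_%d", acc$g, acc$s),
    infrataxon = if (na > 1) sprintf("cv%d", acc$a) else NA_character_,
    infrataxon_rank = if (na > 1) "cultivar" else "none"
  )

  rows <- list()
  for (mk in names(spec$marker_lengths)) {
    L <- spec$marker_lengths[[mk]]
    root <- sample.int(4L, L, replace = TRUE)
    seqs <- character(length(ids))
    i <- 0L
    for (g in seq_len(ng)) {
      g_seq <- mutate_encoded(root, spec$rate_genus, spec$tstv)
      for (s in seq_len(ns)) {
        s_seq <- mutate_encoded(g_seq, spec$rate_species, spec$tstv)
        for (a in seq_len(na)) {
          a_seq <- mutate_encoded(s_seq, spec$rate_accession, spec$tstv)
          i <- i + 1L
          seqs[i] <- paste(bases[a_seq], collapse = "")
        }
      }
    }
    rows[[mk]] <- tibble::tibble(accession_id = ids, marker_id = mk,
                                 sequence = seqs)
  }
  panel <- marker_panel(accessions, names(spec$marker_lengths),
                        dplyr::bind_rows(rows))

  # true genealogy as newick, branch lengths = per-level rates; unary levels
  # (one species per genus, one accession per species) collapse into the
  # parent edge so the tree stays strictly nested
  sp_sub <- function(g, s) {
    if (na == 1) {
      list(str = sprintf("G%d_S%d_A1", g, s), extra = spec$rate_accession)
    } else {
      tips <- sprintf("G%d_S%d_A%d:%g", g, s, seq_len(na), spec$rate_accession)
      list(str = sprintf("(%s)", paste(tips, collapse = ",")), extra = 0)
    }
  }
  g_sub <- function(g) {
    subs <- lapply(seq_len(ns), sp_sub, g = g)
    if (ns == 1) {
      list(str = subs[[1]]$str, extra = spec$rate_species + subs[[1]]$extra)
    } else {
      lab <- sprintf("%s:%g", vapply(subs, `[[`, "", "str"),
                     spec$rate_species + vapply(subs, `[[`, 0, "extra"))
      list(str = sprintf("(%s)", paste(lab, collapse = ",")), extra = 0)
    }
  }
  gs <- lapply(seq_len(ng), g_sub)
  if (ng == 1) {
    nwk <- paste0(gs[[1]]$str, ";")
  } else {
    lab <- sprintf("%s:%g", vapply(gs, `[[`, "", "str"),
                   spec$rate_genus + vapply(gs, `[[`, 0, "extra"))
    nwk <- sprintf("(%s);", paste(lab, collapse = ","))
  }
  genealogy <- ape::read.tree(text = nwk)

  list(panel = panel, genealogy = genealogy)
}
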