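# Composite barcode codes and discrimination statistics.
#
# The composite code of an accession combines L, the total ungapped length of
# its concatenated markers, with the per-marker haplotype labels, e.g.
# "L2127|H1.A|H2.A|H3.A|H4.A" (machine rendering of L^2127 H1^A H2^A H3^A H4^A).
# Two accessions share a code iff they share every marker's haplotype class
# and their total lengths agree.

render_code <- function(total_length_bp, labels) {
  paste0("L", total_length_bp, "|",
         paste(sub("^", ".", labels, fixed = TRUE), collapse = "|"))
}

#' Build composite barcodes for all accessions of a panel
#'
#' @param panel A [marker_panel()].
#' @param assignments Optional named list of haplotype assignments (one per
#'   marker, as from [collapse_all()]); computed from the panel if omitted.
#' @return Tibble of class `barcode_db`, one row per accession:
#'   `accession_id`, `genus`, `species`, `infrataxon`, one `len_<marker>`
#'   column per marker (ungapped bp), `total_length_bp`, one `hap_<marker>`
#'   label column per marker, and `code_string`.
#' @examples
#' panel <- generate_fixture(seed = 1)
#' b <- build_barcodes(panel)
#' b$code_string[b$accession_id == "AGC_CRI"] # "L2127|H1.A|H2.A|H3.A|H4.A"
#' @export
build_barcodes <- function(panel, assignments = NULL) {
  if (is.null(assignments)) assignments <- collapse_all(panel)
  markers <- panel$markers$marker_id
  missing_mk <- setdiff(markers, purrr::map_chr(assignments, "marker_id"))
  if (length(missing_mk) > 0) {
    stop_validation("no haplotype assignment supplied for marker '%s'", missing_mk[1])
  }
  assignments <- assignments[match(markers, purrr::map_chr(assignments, "marker_id"))]
  names(assignments) <- markers

  acc <- panel$accessions
  per_marker <- purrr::map(assignments, function(a) {
    i <- match(acc$accession_id, a$membership$accession_id)
    if (anyNA(i)) {
      stop_validation("accession '%s' missing from assignment of marker '%s'",
                      acc$accession_id[which(is.na(i))[1]], a$marker_id)
    }
    a$membership[i, c("label", "length_bp")]
  })

  lens <- purrr::map(per_marker, "length_bp")
  labs <- purrr::map(per_marker, "label")
  total <- Reduce(`+`, lens)

  out <- tibble::tibble(
    accession_id = acc$accession_id,
    genus = acc$genus,
    species = acc$species,
    infrataxon = acc$infrataxon
  )
  for (m in markers) out[[paste0("len_", m)]] <- lens[[m]]
  out$total_length_bp <- total
  for (m in markers) out[[paste0("hap_", m)]] <- labs[[m]]
  out$code_string <- purrr::map_chr(seq_len(nrow(out)), function(i) {
    render_code(total[i], purrr::map_chr(labs, i))
  })
  class(out) <- c("barcode_db", class(out))
  attr(out, "markers") <- markers
  out
}

#' Build the composite barcode of a single accession
#'
#' @inheritParams build_barcodes
#' @param accession_id Accession to look up.
#' @return One-row tibble (see [build_barcodes()]).
#' @export
build_barcode <- function(panel, assignments = NULL, accession_id) {
  db <- build_barcodes(panel, assignments)
  row <- db[db$accession_id == accession_id, ]
  if (nrow(row) == 0) {
    stop_validation("unknown accession '%s'", accession_id)
  }
  row
}

# Accession -> discriminating key (haplotype label or composite code string).
discrimination_keys <- function(x) {
  if (inherits(x, "haplotype_assignment")) {
    setNames(x$membership$label, x$membership$accession_id)
  } else if (inherits(x, "barcode_db")) {
    setNames(x$code_string, x$accession_id)
  } else {
    stop_validation("expected a haplotype_assignment or a barcode_db")
  }
}

check_units <- function(units, known_ids) {
  if (length(units) == 0) stop_validation("evaluation unit list is empty")
  sizes <- lengths(units)
  if (any(sizes == 0)) stop_validation("evaluation units must be non-empty")
  all_ids <- unlist(units, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop_validation("evaluation units overlap on accession '%s'",
                    all_ids[duplicated(all_ids)][1])
  }
  unknown <- setdiff(all_ids, known_ids)
  if (length(unknown) > 0) {
    stop_validation("evaluation unit names unknown accession '%s'", unknown[1])
  }
  all_ids
}

#' Number of taxa resolved by a barcode
#'
#' Counts the distinct haplotype classes (single marker) or composite codes
#' (combined barcode) observed across the accessions of the evaluation units:
#' the "resolving N accessions" statistic. Units group accessions that are
#' regarded as one terminal taxon (e.g. conspecific cultivars).
#'
#' @param x A `haplotype_assignment` or a `barcode_db`.
#' @param evaluation_units List of disjoint, non-empty character vectors of
#'   accession ids (see [taxon_units()]).
#' @return Integer count of distinct classes/codes.
#' @export
resolve_count <- function(x, evaluation_units) {
  keys <- discrimination_keys(x)
  ids <- check_units(evaluation_units, names(keys))
  dplyr::n_distinct(keys[ids])
}

#' Species-level assignment success of a barcode
#'
#' The correct assignment rate: `100 * distinct classes (or codes) / number
#' of taxa`, reported to one decimal place (half-up). With one accession per
#' taxon this is the fraction of taxa carrying their own haplotype class,
#' e.g. 7 classes among 8 species gives 87.5.
#'
#' @param x A `haplotype_assignment` or a `barcode_db`.
#' @param taxa List of disjoint species-level accession groups covering the
#'   evaluation set.
#' @return Percentage in (0, 100] (can exceed 100 if taxa are internally
#'   polymorphic), rounded to one decimal.
#' @export
assignment_success <- function(x, taxa) {
  n <- resolve_count(x, taxa)
  round_half_up(100 * n / length(taxa), 1)
}

unresolved_code_groups <- function(barcodes) {
  grp <- split(barcodes$accession_id, barcodes$code_string)
  grp <- grp[lengths(grp) > 1]
  unname(grp[order(purrr::map_chr(grp, 1))])
}

level_summary <- function(assignments, barcodes, units, level_name) {
  rows <- purrr::map_dfr(assignments, function(a) {
    tibble::tibble(level = level_name, barcode = a$marker_id,
                   resolved = resolve_count(a, units))
  })
  rows <- dplyr::bind_rows(
    rows,
    tibble::tibble(level = level_name, barcode = "combined",
                   resolved = resolve_count(barcodes, units))
  )
  rows$n_units <- length(units)
  rows$success <- round_half_up(100 * rows$resolved / rows$n_units, 1)
  rows
}

#' Discrimination report across taxonomic levels
#'
#' Scores every single-marker barcode and the combined composite code at
#' three levels: across the full panel (terminal taxa = species or named
#' varieties, conspecific cultivars pooled), within each genus (units = the
#' genus's terminal taxa), and within each species (units = its accessions,
#' i.e. cultivar-level discrimination). Unresolved groups -- accessions
#' sharing one composite code -- are listed explicitly.
#'
#' @param panel A [marker_panel()].
#' @param assignments Optional list of haplotype assignments (computed if
#'   omitted).
#' @return Object of class `discrimination_report`: list with `summary`
#'   (tibble over levels/barcodes), `per_marker_resolved`,
#'   `per_marker_assignment_success`, `combined_resolved`,
#'   `combined_assignment_success` (all at the terminal-taxon level),
#'   `unresolved_groups`, `within_genus`, `within_species`, `n_accessions`,
#'   `n_taxa`.
#' @export
discrimination_report <- function(panel, assignments = NULL) {
  if (is.null(assignments)) assignments <- collapse_all(panel)
  barcodes <- build_barcodes(panel, assignments)

  units_taxon <- taxon_units(panel, "taxon")
  top <- level_summary(assignments, barcodes, units_taxon, "panel")

  acc <- panel$accessions
  genus_groups <- split(seq_len(nrow(acc)), acc$genus)
  within_genus <- purrr::imap_dfr(genus_groups, function(rows, g) {
    sub <- acc[rows, ]
    key <- ifelse(sub$infrataxon_rank == "variety",
                  paste(sub$genus, sub$species, "var.", sub$infrataxon),
                  paste(sub$genus, sub$species))
    units <- split(sub$accession_id, factor(key, levels = unique(key)))
    if (length(units) < 2) return(NULL)
    out <- level_summary(assignments, barcodes, units, "within_genus")
    out$genus <- g
    out
  })

  species_groups <- split(seq_len(nrow(acc)), paste(acc$genus, acc$species))
  within_species <- purrr::imap_dfr(species_groups, function(rows, sp) {
    sub <- acc[rows, ]
    units <- as.list(sub$accession_id)
    if (length(units) < 2) return(NULL)
    out <- level_summary(assignments, barcodes, units, "within_species")
    out$species <- sp
    out
  })

  marker_rows <- top[top$barcode != "combined", ]
  res <- structure(
    list(
      summary = dplyr::bind_rows(top, within_genus, within_species),
      per_marker_resolved = setNames(marker_rows$resolved, marker_rows$barcode),
      per_marker_assignment_success = setNames(marker_rows$success, marker_rows$barcode),
      combined_resolved = top$resolved[top$barcode == "combined"],
      combined_assignment_success = top$success[top$barcode == "combined"],
      unresolved_groups = unresolved_code_groups(barcodes),
      within_genus = within_genus,
      within_species = within_species,
      n_accessions = nrow(acc),
      n_taxa = length(units_taxon)
    ),
    class = "discrimination_report"
  )
  res
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf("<discrimination_report> %d accessions, %d terminal taxa\n",
              x$n_accessions, x$n_taxa))
  print(x$summary[x$summary$level == "panel",
                  c("barcode", "resolved", "n_units", "success")])
  if (length(x$unresolved_groups) > 0) {
    cat("unresolved composite-code groups:\n")
    for (g in x$unresolved_groups) cat("  {", paste(g, collapse = ", "), "}\n")
  } else {
    cat("no unresolved composite-code groups\n")
  }
  invisible(x)
}

#' Serialize a discrimination report to JSON
#'
#' @param report A `discrimination_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_discrimination_report <- function(report, path) {
  payload <- list(
    n_accessions = report$n_accessions,
    n_taxa = report$n_taxa,
    per_marker_resolved = as.list(report$per_marker_resolved),
    per_marker_assignment_success = as.list(report$per_marker_assignment_success),
    combined_resolved = report$combined_resolved,
    combined_assignment_success = report$combined_assignment_success,
    unresolved_groups = report$unresolved_groups,
    summary = report$summary
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write the barcode database as a tab-separated table
#'
#' Mirrors the published database layout: taxonomy columns, per-marker
#' lengths, total length, per-marker haplotype labels, composite code.
#'
#' @param barcodes A `barcode_db`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_barcode_table <- function(barcodes, path) {
  readr::write_tsv(tibble::as_tibble(barcodes), path, na = "")
  invisible(path)
}
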