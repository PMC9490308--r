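# broom-style tidiers and ggplot2 autoplot methods for the tabular results.

#' @rdname tidy_haplocode
#' @method tidy marker_panel
#' @export
tidy.marker_panel <- function(x, ...) {
  dplyr::left_join(x$sequences, x$accessions, by = "accession_id") |>
    dplyr::mutate(length_bp = ungapped_length(.data$sequence)) |>
    dplyr::select("accession_id", "genus", "species", "infrataxon",
                  "infrataxon_rank", "marker_id", "length_bp", "sequence")
}

#' Tidy summaries of haplocode objects
#'
#' `tidy()` returns one observation per row: per-accession haplotype
#' membership for a `haplotype_assignment`, per-sequence records for a
#' `marker_panel`, pairwise entries for a `dist_matrix`, and the level-wise
#' summary for a `discrimination_report`. `glance()` on a
#' `discrimination_report` returns its one-row headline numbers.
#'
#' @param x Object to tidy.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_haplocode
#' @method tidy haplotype_assignment
#' @export
tidy.haplotype_assignment <- function(x, ...) {
  dplyr::mutate(x$membership, marker_id = x$marker_id, .before = 1)
}

#' @rdname tidy_haplocode
#' @method tidy dist_matrix
#' @export
tidy.dist_matrix <- function(x, ...) {
  ids <- x$accession_ids
  pairs <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    from = ids[pairs[, 1]],
    to = ids[pairs[, 2]],
    distance = x$values[pairs],
    sites = x$site_counts[pairs],
    undefined = x$undefined[pairs],
    model = x$model
  )
}

#' @rdname tidy_haplocode
#' @method tidy discrimination_report
#' @export
tidy.discrimination_report <- function(x, ...) {
  x$summary
}

#' @rdname tidy_haplocode
#' @method glance discrimination_report
#' @export
glance.discrimination_report <- function(x, ...) {
  tibble::tibble(
    n_accessions = x$n_accessions,
    n_taxa = x$n_taxa,
    combined_resolved = x$combined_resolved,
    combined_assignment_success = x$combined_assignment_success,
    n_unresolved_groups = length(x$unresolved_groups)
  )
}

#' Plot discrimination power by barcode
#'
#' Bar chart of taxa resolved by each single-marker barcode and the combined
#' composite code at the panel level.
#'
#' @param object A `discrimination_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot discrimination_report
#' @export
autoplot.discrimination_report <- function(object, ...) {
  d <- object$summary[object$summary$level == "panel", ]
  d$barcode <- factor(d$barcode, levels = d$barcode)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$barcode, y = .data$resolved,
                                  fill = .data$barcode == "combined")) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = d$n_units[1], linetype = 2) +
    ggplot2::labs(x = NULL, y = "taxa resolved",
                  title = "Discrimination power by barcode",
                  subtitle = sprintf("dashed line: %d terminal taxa", d$n_units[1])) +
    ggplot2::theme_minimal()
}

#' Plot a pairwise distance matrix as a heatmap
#'
#' @param object A `dist_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dist_matrix
#' @export
autoplot.dist_matrix <- function(object, ...) {
  d <- tidy.dist_matrix(object)
  lv <- object$accession_ids
  d$from <- factor(d$from, levels = lv)
  d$to <- factor(d$to, levels = lv)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$from, y = .data$to,
                                  fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = object$model,
                  title = "Pairwise distances") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
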