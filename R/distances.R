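# Pairwise evolutionary distances on aligned sequences with pairwise deletion:
# p-distance, number of differences, Kimura two-parameter (K2P), and
# gamma-rate-corrected K2P. Sites where either sequence carries a gap or an
# ambiguity code are excluded pair by pair ("pairwise deletion").

DIST_MODELS <- c("p", "num_diff", "k2p", "k2p_gamma", "num_diff_gamma")

# Encode an alignment as an integer matrix (rows = taxa, cols = sites):
# A=1, G=2, C=3, T=4; gaps and ambiguity codes become NA. Purines are <= 2,
# pyrimidines >= 3, so a substitution is a transition iff both codes fall on
# the same side of that split.
encode_alignment <- function(block) {
  seqs <- unclass(block)
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE)
  code <- matrix(match(mat, c("A", "G", "C", "T")), nrow = nrow(mat))
  rownames(code) <- names(seqs)
  code
}

pair_stats_enc <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n == 0) {
    return(list(n = 0L, P = NA_real_, Q = NA_real_, diffs = NA_integer_))
  }
  x <- x[ok]; y <- y[ok]
  diff <- x != y
  ts <- diff & ((x <= 2) == (y <= 2))   # A<->G or C<->T
  d <- sum(diff)
  list(n = n, P = sum(ts) / n, Q = (d - sum(ts)) / n, diffs = as.integer(d))
}

#' Comparable sites and substitution proportions of a sequence pair
#'
#' Scans two equal-length gapped sequences, drops every site where either
#' carries a gap or a non-ACGT character (pairwise deletion), and returns the
#' number of comparable sites together with the proportions of transitions
#' (`P`: A/G or C/T) and transversions (`Q`) among them.
#'
#' @param a,b Equal-length sequence strings.
#' @return List with `n` (comparable sites), `P`, `Q`, and `diffs` (count of
#'   differing comparable sites). When `n` is 0 the pair is undefined and
#'   `P`, `Q`, `diffs` are NA.
#' @examples
#' pairwise_sites("A-GT", "AAGA") # n = 3, P = 0, Q = 1/3
#' @export
pairwise_sites <- function(a, b) {
  a <- sanitize_sequence(a); b <- sanitize_sequence(b)
  if (nchar(a) != nchar(b)) {
    stop_validation("sequences have different lengths (%d vs %d)", nchar(a), nchar(b))
  }
  enc <- encode_alignment(aligned_block(c(a. = a, b. = b)))
  pair_stats_enc(enc[1, ], enc[2, ])
}

#' Kimura two-parameter distance
#'
#' Without rate variation: `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.
#' With gamma-distributed rate variation of shape `a`:
#' `d = a/2 * ((1 - 2P - Q)^(-1/a) + 1/2 (1 - 2Q)^(-1/a) - 3/2)`.
#' Saturated pairs (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) yield `NA` rather
#' than an error so that a whole matrix can complete and flag them.
#'
#' @param P Transition proportion (vectorized).
#' @param Q Transversion proportion.
#' @param gamma_shape Optional positive gamma shape parameter.
#' @return Numeric distance(s); `NA` where saturated.
#' @export
k2p_distance <- function(P, Q, gamma_shape = NULL) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- rep(NA_real_, length(w1))
  ok <- !is.na(w1) & !is.na(w2) & w1 > 0 & w2 > 0
  if (is.null(gamma_shape)) {
    d[ok] <- -0.5 * log(w1[ok]) - 0.25 * log(w2[ok])
  } else {
    if (!is.numeric(gamma_shape) || length(gamma_shape) != 1 || gamma_shape <= 0) {
      stop_validation("gamma_shape must be a single positive number")
    }
    a <- gamma_shape
    d[ok] <- (a / 2) * (w1[ok]^(-1 / a) + 0.5 * w2[ok]^(-1 / a) - 1.5)
  }
  d
}

#' Number of base differences between two aligned sequences
#'
#' Counts comparable sites (pairwise deletion, as in [pairwise_sites()])
#' at which the two sequences differ.
#'
#' @inheritParams pairwise_sites
#' @return Integer count; `NA` if no site is comparable.
#' @export
num_differences <- function(a, b) {
  pairwise_sites(a, b)$diffs
}

#' Pairwise distance matrix of an aligned block
#'
#' @param block An [aligned_block()] (>= 2 sequences).
#' @param model One of `"p"` (proportion of differing sites), `"num_diff"`
#'   (count of differing sites), `"k2p"`, `"k2p_gamma"`, `"num_diff_gamma"`.
#'   The `num_diff_gamma` model returns the raw count: a gamma rate
#'   correction is not defined for an uncorrected count, so the shape
#'   parameter is accepted for interface compatibility and ignored (with a
#'   warning).
#' @param gamma_shape Gamma shape parameter for `k2p_gamma` (default 1, the
#'   conventional tree-building setting).
#' @return Object of class `dist_matrix`: list with `values` (symmetric
#'   matrix, `NA` where undefined), `site_counts`, `undefined` (logical
#'   matrix: saturation or zero comparable sites), `model`, `gamma_shape`,
#'   `accession_ids`.
#' @export
distance_matrix <- function(block, model = c("k2p", "p", "num_diff",
                                             "k2p_gamma", "num_diff_gamma"),
                            gamma_shape = NULL) {
  model <- match.arg(model)
  if (!inherits(block, "aligned_block")) block <- aligned_block(block)
  n <- length(block)
  if (n < 2) stop_validation("distance matrix needs at least 2 sequences")
  if (model == "k2p_gamma" && is.null(gamma_shape)) gamma_shape <- 1
  if (model == "num_diff_gamma") {
    rlang::warn(paste("gamma rate correction is undefined for a raw difference",
                      "count; computing plain number of differences"))
  }
  if (!model %in% c("k2p_gamma")) gamma_shape_used <- NULL else gamma_shape_used <- gamma_shape

  enc <- encode_alignment(block)
  ids <- rownames(enc)
  values <- matrix(0, n, n, dimnames = list(ids, ids))
  counts <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  diag(counts) <- as.integer(rowSums(!is.na(enc)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      st <- pair_stats_enc(enc[i, ], enc[j, ])
      counts[i, j] <- counts[j, i] <- st$n
      v <- if (st$n == 0) {
        NA_real_
      } else if (model %in% c("k2p", "k2p_gamma")) {
        k2p_distance(st$P, st$Q, gamma_shape_used)
      } else if (model == "p") {
        st$diffs / st$n
      } else {
        as.numeric(st$diffs)
      }
      values[i, j] <- values[j, i] <- v
    }
  }
  structure(
    list(values = values, site_counts = counts, undefined = is.na(values),
         model = model, gamma_shape = gamma_shape_used, accession_ids = ids),
    class = "dist_matrix"
  )
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d taxa, model %s%s, %d undefined pair(s)\n",
              length(x$accession_ids), x$model,
              if (!is.null(x$gamma_shape)) sprintf(" (gamma shape %g)", x$gamma_shape) else "",
              sum(x$undefined[upper.tri(x$undefined)])))
  print(round(x$values, 4))
  invisible(x)
}

#' @export
as.matrix.dist_matrix <- function(x, ...) x$values

#' @export
as.dist.dist_matrix <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$values, diag = diag, upper = upper)
}

#' Write a distance matrix
#'
#' @param dm A `dist_matrix`.
#' @param path Output path.
#' @param format `"phylip"` for a square PHYLIP-style matrix, `"long"` for a
#'   tab-separated long table (`from`, `to`, `distance`, `sites`).
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(dm, path, format = c("phylip", "long")) {
  format <- match.arg(format)
  if (format == "phylip") {
    n <- length(dm$accession_ids)
    lines <- c(sprintf("%5d", n),
               vapply(seq_len(n), function(i) {
                 paste(c(format(dm$accession_ids[i], width = 12),
                         sprintf("%.8f", dm$values[i, ])), collapse = "  ")
               }, character(1)))
    writeLines(lines, path)
  } else {
    readr::write_tsv(tidy.dist_matrix(dm), path)
  }
  invisible(path)
}
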