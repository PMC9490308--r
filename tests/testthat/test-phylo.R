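random_additive_tree <- function(n) {
  tr <- ape::unroot(ape::rtree(n, br = function(k) stats::runif(k, 0.1, 2)))
  tr
}

test_that("marker blocks concatenate with recorded offsets", {
  mk_block <- function(id, len, n = 3) {
    seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""))
    aligned_block(setNames(seqs, paste0("t", 1:n)))
  }
  set.seed(41)
  blocks <- list(a = mk_block("a", 400), b = mk_block("b", 572), c = mk_block("c", 470))
  cc <- concatenate_blocks(blocks)
  off <- attr(cc, "offsets")
  expect_equal(attr(cc, "width"), 1442)
  expect_equal(off$start, c(0, 400, 972))
  expect_equal(off$end, c(400, 972, 1442))

  one <- concatenate_blocks(blocks["a"])
  expect_equal(unclass(one)[names(blocks$a)], unclass(blocks$a)[names(blocks$a)])

  bad <- blocks
  names(bad$c) <- c("t1", "t2", "tX")
  expect_error(concatenate_blocks(bad), "tX|t3",
               class = "haplocode_validation_error")
})

test_that("the fixture's concatenated barcode length matches its composite code", {
  p <- fixture_panel()
  blocks <- setNames(lapply(grass_markers, panel_alignment, panel = p), grass_markers)
  cc <- concatenate_blocks(blocks)
  expect_equal(nchar(gsub("-", "", cc[["AGC_CRI"]], fixed = TRUE)), 2127)
})

test_that("NJ solves the 3-taxon star in closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["A"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["B"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["C"]], (4 + 5 - 3) / 2)
})

test_that("NJ recovers additive trees exactly and matches an independent NJ", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    truth <- random_additive_tree(n)
    D <- ape::cophenetic.phylo(truth)
    tr <- nj_tree(D)
    expect_equal(as.numeric(ape::dist.topo(tr, truth)), 0)
    expect_equal(total_branch_length(tr), sum(truth$edge.length),
                 tolerance = 1e-9)
    # branch lengths agree edge-for-edge via patristic distances
    expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9)
    # cross-check against ape's NJ topology
    tr_ape <- ape::unroot(ape::nj(stats::as.dist(D)))
    expect_equal(as.numeric(ape::dist.topo(tr, tr_ape)), 0)
  }
})

test_that("leaf permutation yields an isomorphic tree", {
  set.seed(43)
  truth <- random_additive_tree(7)
  D <- ape::cophenetic.phylo(truth)
  perm <- sample(nrow(D))
  tr1 <- nj_tree(D)
  tr2 <- nj_tree(D[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(tr1, tr2)), 0)
})

test_that("all-equal distances resolve by the lowest-index tie rule", {
  d <- matrix(1, 5, 5, dimnames = list(paste0("t", 1:5), paste0("t", 1:5)))
  diag(d) <- 0
  tr <- nj_tree(d)
  expect_true(is_monophyletic(tr, c("t1", "t2")))
  # deterministic: repeated runs identical
  expect_identical(ape::write.tree(tr), ape::write.tree(nj_tree(d)))
})

test_that("degenerate and invalid inputs are handled", {
  d2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr2 <- nj_tree(d2)
  expect_equal(sort(tr2$tip.label), c("a", "b"))
  expect_equal(total_branch_length(tr2), 4)

  blk <- aligned_block(c(x = "AC--", y = "--AC", z = "ACGT"))
  dm <- distance_matrix(blk, "p")
  expect_error(nj_tree(dm), "undefined", class = "haplocode_computation_error")
})

test_that("negative branch estimates are clamped to zero", {
  set.seed(44)
  clamped_seen <- FALSE
  for (rep in 1:30) {
    n <- 6
    D <- matrix(0, n, n, dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
    v <- stats::runif(n * (n - 1) / 2, 0.1, 1)
    D[upper.tri(D)] <- v
    D <- D + t(D)
    tr <- suppressMessages(nj_tree(D))
    expect_true(all(tr$edge.length >= 0))
    if (attr(tr, "clamped") > 0) clamped_seen <- TRUE
  }
  expect_true(clamped_seen)
})

test_that("monophyly is decided by induced bipartitions", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(is_monophyletic(tr, "A"))
  expect_true(is_monophyletic(tr, c("A", "B", "C", "D")))
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_error(is_monophyletic(tr, "Z"), "Z",
               class = "haplocode_validation_error")
  expect_error(is_monophyletic(tr, character(0)), "empty",
               class = "haplocode_validation_error")
  # agreement with ape on random trees
  set.seed(45)
  for (rep in 1:20) {
    tr <- ape::unroot(ape::rtree(8))
    grp <- sample(tr$tip.label, sample(2:6, 1))
    expect_equal(is_monophyletic(tr, grp),
                 ape::is.monophyletic(tr, grp))
  }
})

test_that("bootstrap support is deterministic and bounded", {
  p <- fixture_panel()
  blk <- panel_alignment(p, "ITS")
  bt1 <- bootstrap_support(blk, "num_diff", replicates = 60, seed = 9)
  bt2 <- bootstrap_support(blk, "num_diff", replicates = 60, seed = 9)
  expect_identical(bt1$node.label, bt2$node.label)
  sup <- bt1$node.label[!is.na(bt1$node.label)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_error(bootstrap_support(blk, replicates = 0, seed = 1), "replicates",
               class = "haplocode_validation_error")
  expect_error(bootstrap_support(blk, replicates = 10), "seed",
               class = "haplocode_validation_error")
})

test_that("conflict-free signal earns near-certain support", {
  # 4 taxa, many identical columns supporting the AB|CD split, no conflict
  col_ab <- c(A = "A", B = "A", C = "T", D = "T")
  mat <- cbind(matrix(rep(col_ab, 120), nrow = 4),
               matrix("G", nrow = 4, ncol = 2))  # constant tail columns
  seqs <- apply(mat, 1, paste, collapse = "")
  blk <- aligned_block(setNames(seqs, names(col_ab)))
  bt <- bootstrap_support(blk, "num_diff", replicates = 400, seed = 10)
  expect_gte(max(bt$node.label, na.rm = TRUE), 98)
})

test_that("Monte-Carlo bootstrap converges to the exhaustive expectation", {
  # 2 informative columns, 4 taxa: the 4 equally likely ordered resamples are
  # enumerable, giving the exact expected support for each original split
  seqs <- c(A = "AA", B = "AT", C = "TA", D = "TT")
  blk <- aligned_block(seqs)
  enc <- haplocode:::encode_alignment(blk)
  base <- nj_tree(distance_matrix(blk, "num_diff"))
  keys <- haplocode:::tree_bipartitions(base)
  outcomes <- list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  hits <- vapply(outcomes, function(cols) {
    d <- haplocode:::dist_from_encoded(enc[, cols, drop = FALSE], "num_diff")
    keys %in% haplocode:::tree_bipartitions(suppressMessages(nj_tree(d)))
  }, logical(length(keys)))
  exact <- rowMeans(matrix(hits, nrow = length(keys))) * 100
  bt <- bootstrap_support(blk, "num_diff", replicates = 4000, seed = 11)
  got <- bt$node.label[!is.na(bt$node.label)]
  expect_true(all(abs(got - unname(exact)) <= 3))
})

test_that("Newick output round-trips topology, lengths and supports", {
  p <- fixture_panel()
  blk <- panel_alignment(p, "matK")
  bt <- bootstrap_support(blk, "num_diff", replicates = 50, seed = 12)
  f1 <- withr::local_tempfile(fileext = ".nwk")
  f2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(bt, f1)
  back <- read_newick(f1)
  write_newick_chr <- function(tr, f) { write_newick(tr, f); readLines(f) }
  expect_identical(readLines(f1), write_newick_chr(back, f2))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(back), ape::unroot(bt))), 0)
  # supports appear after internal closing parens
  expect_match(readLines(f1), "\\)[0-9]+:")

  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  f3 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(nj_tree(d), f3)
  expect_match(readLines(f3), "^\\(A:[0-9.]+,B:[0-9.]+,C:[0-9.]+\\);$")

  bad <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1", bad)
  expect_error(read_newick(bad), "malformed",
               class = "haplocode_validation_error")
})
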