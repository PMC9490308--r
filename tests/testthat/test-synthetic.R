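test_that("the fixture realizes the printed lengths cell for cell", {
  spec <- grass_fixture_spec()
  p <- fixture_panel()
  got <- p$sequences
  got$length_bp <- nchar(gsub("-", "", got$sequence, fixed = TRUE))
  merged <- merge(got[c("accession_id", "marker_id", "length_bp")],
                  spec$haplotypes,
                  by = c("accession_id", "marker_id"),
                  suffixes = c("_got", "_want"))
  expect_equal(nrow(merged), 56)
  expect_equal(merged$length_bp_got, merged$length_bp_want)
})

test_that("fixture sequences are identical iff their printed labels coincide", {
  spec <- grass_fixture_spec()
  for (seed in c(1, 7, 2024)) {
    p <- generate_fixture(spec, seed = seed)
    for (mk in spec$markers) {
      h <- collapse_haplotypes(p, mk)
      sub <- spec$haplotypes[spec$haplotypes$marker_id == mk, ]
      m <- merge(h$membership, sub, by = "accession_id")
      # the computed partition and the printed letters induce the same grouping
      tab <- table(m$letter, m$class_letter)
      expect_equal(sum(tab > 0), nrow(h$classes))
      expect_equal(nrow(h$classes), length(unique(sub$class_letter)))
    }
  }
})

test_that("distinct fixture classes respect the minimum divergence", {
  spec <- grass_fixture_spec()
  p <- generate_fixture(spec, seed = 5, min_class_divergence = 3)
  for (mk in spec$markers) {
    blk <- panel_alignment(p, mk)
    dm <- distance_matrix(blk, "num_diff")
    h <- collapse_haplotypes(p, mk)
    lab <- setNames(h$membership$label, h$membership$accession_id)
    ids <- names(blk)
    for (i in seq_along(ids)[-1]) for (j in seq_len(i - 1)) {
      if (lab[[ids[i]]] != lab[[ids[j]]]) {
        expect_gte(dm$values[ids[i], ids[j]], 3)
      }
    }
  }
})

test_that("fixture generation is byte-identical under a fixed seed", {
  p1 <- generate_fixture(seed = 123)
  p2 <- generate_fixture(seed = 123)
  expect_identical(p1$sequences, p2$sequences)
  p3 <- generate_fixture(seed = 124)
  expect_false(identical(p1$sequences, p3$sequences))
})

test_that("fixture spec validation catches malformed inputs", {
  spec <- grass_fixture_spec()
  broken <- spec
  broken$haplotypes <- broken$haplotypes[-1, ]
  expect_error(generate_fixture(broken), "missing cell",
               class = "haplocode_validation_error")
  relabel <- spec
  # letters no longer start at A for the first accession of ITS
  relabel$haplotypes$class_letter[
    relabel$haplotypes$marker_id == "ITS" &
      relabel$haplotypes$accession_id == relabel$accessions$accession_id[1]
  ] <- "Z"
  expect_error(generate_fixture(relabel), "canonical",
               class = "haplocode_validation_error")
  expect_error(generate_fixture(spec, min_class_divergence = 0), ">= 1",
               class = "haplocode_validation_error")
  expect_error(generate_fixture(list()), "fixture_spec",
               class = "haplocode_validation_error")
})

test_that("zero substitution rates simulate an invariant panel", {
  spec <- simulation_spec(n_genera = 2, species_per_genus = 2,
                          accessions_per_species = 2,
                          marker_lengths = c(m1 = 80),
                          rate_genus = 0, rate_species = 0,
                          rate_accession = 0)
  sim <- simulate_panel(spec, seed = 2)
  h <- collapse_haplotypes(sim$panel, "m1")
  expect_equal(nrow(h$classes), 1)
})

test_that("simulation is deterministic and requires a seed", {
  spec <- simulation_spec(n_genera = 3, marker_lengths = c(m1 = 60, m2 = 40))
  s1 <- simulate_panel(spec, seed = 9)
  s2 <- simulate_panel(spec, seed = 9)
  expect_identical(s1$panel$sequences, s2$panel$sequences)
  expect_identical(ape::write.tree(s1$genealogy), ape::write.tree(s2$genealogy))
  expect_error(simulate_panel(spec), "seed",
               class = "haplocode_validation_error")
})

test_that("divergence grows with the species-level rate", {
  mean_within_genus_diff <- function(rate, seed) {
    spec <- simulation_spec(n_genera = 2, species_per_genus = 2,
                            accessions_per_species = 1,
                            marker_lengths = c(m1 = 400),
                            rate_genus = 0, rate_species = rate,
                            rate_accession = 0)
    sim <- simulate_panel(spec, seed = seed)
    dm <- distance_matrix(panel_alignment(sim$panel, "m1"), "num_diff")
    mean(c(dm$values["G1_S1_A1", "G1_S2_A1"], dm$values["G2_S1_A1", "G2_S2_A1"]))
  }
  rates <- c(0, 0.01, 0.05, 0.2)
  avg <- vapply(rates, function(r) {
    mean(vapply(1:5, function(s) mean_within_genus_diff(r, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(avg) > 0))
})

test_that("species resolution is non-decreasing in the species-level rate", {
  count_at <- function(rate, seed) {
    spec <- simulation_spec(n_genera = 3, species_per_genus = 2,
                            accessions_per_species = 2,
                            marker_lengths = c(m1 = 300),
                            rate_genus = 0.05, rate_species = rate,
                            rate_accession = 0)
    sim <- simulate_panel(spec, seed = seed)
    units <- split(sim$panel$accessions$accession_id,
                   sim$panel$accessions$species)
    resolve_count(collapse_haplotypes(sim$panel, "m1"), unname(units))
  }
  for (seed in 1:4) {
    counts <- vapply(c(0, 0.02, 0.1), count_at, integer(1), seed = seed)
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("the simulated genealogy carries exactly the panel's accessions", {
  spec <- simulation_spec(n_genera = 4, species_per_genus = 3,
                          accessions_per_species = 2,
                          marker_lengths = c(m1 = 50))
  sim <- simulate_panel(spec, seed = 4)
  expect_setequal(sim$genealogy$tip.label, sim$panel$accessions$accession_id)
  expect_equal(ape::Ntip(sim$genealogy), 24)
  # unary levels collapse but the leaf set survives
  spec1 <- simulation_spec(n_genera = 3, species_per_genus = 1,
                           accessions_per_species = 1,
                           marker_lengths = c(m1 = 50))
  sim1 <- simulate_panel(spec1, seed = 4)
  expect_setequal(sim1$genealogy$tip.label, sim1$panel$accessions$accession_id)
})

test_that("simulation_spec rejects invalid parameters", {
  expect_error(simulation_spec(n_genera = 0), ">= 1",
               class = "haplocode_validation_error")
  expect_error(simulation_spec(rate_genus = -0.1), ">= 0",
               class = "haplocode_validation_error")
  expect_error(simulation_spec(tstv = 0), "tstv",
               class = "haplocode_validation_error")
  expect_error(simulation_spec(marker_lengths = c(100)), "named",
               class = "haplocode_validation_error")
})
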