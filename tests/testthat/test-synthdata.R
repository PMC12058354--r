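test_that("reference sequences respect the divergence bands", {
  spec <- sim_spec(n_orders = 1L, families_per_order = 2L,
                   genera_per_family = 1L, species_per_genus = 2L,
                   seed = 12)
  ref <- make_reference(spec)
  expect_length(ref$sequences, 4L)
  lin <- ref$lineages
  expect_false(anyNA(lin[, c("phylum", "class", "order", "family",
                             "genus", "species")]))
  for (i in 1:3) {
    for (j in (i + 1):4) {
      ident <- pairwise_identity(ref$sequences[[i]], ref$sequences[[j]])
      if (lin$genus[i] == lin$genus[j]) {
        expect_gte(ident, 98)
      } else if (lin$family[i] != lin$family[j]) {
        expect_lte(ident, 90)
      }
    }
  }
  single <- make_reference(sim_spec(n_orders = 1L, families_per_order = 1L,
                                    genera_per_family = 1L,
                                    species_per_genus = 1L))
  expect_length(single$sequences, 1L)

  # generators are bit-reproducible given (spec, seed)
  expect_identical(make_reference(spec), ref)
})

test_that("reference FASTA headers round-trip through the lineage parser", {
  ref <- make_reference(sim_spec(n_orders = 1L, families_per_order = 1L,
                                 genera_per_family = 2L,
                                 species_per_genus = 1L, seed = 4))
  path <- tempfile(fileext = ".fasta")
  write_reference_fasta(ref, path)
  lmap <- read_lineage_map(path)
  expect_equal(lmap$subject_id, ref$lineages$subject_id)
  expect_equal(lmap$species, ref$lineages$species)
  expect_equal(lmap$family, ref$lineages$family)
})

test_that("zero-error reads equal their templates; counts match ground truth", {
  spec <- sim_spec(n_orders = 1L, families_per_order = 1L,
                   genera_per_family = 1L, species_per_genus = 2L,
                   sub_rate = 0, ins_rate = 0, del_rate = 0,
                   low_q_fraction = 0, seed = 5)
  ref <- make_reference(spec)
  ab <- data.frame(sample_id = c("s1", "s1", "s2"),
                   taxon_id = names(ref$sequences)[c(1, 2, 1)],
                   reads = c(3L, 2L, 4L))
  sim <- simulate_reads(ref, ab, spec)
  expect_equal(nrow(sim$reads), sum(ab$reads))
  expect_equal(nrow(sim$truth), sum(ab$reads))
  for (i in seq_len(nrow(sim$reads))) {
    expect_equal(sim$reads$sequence[i],
                 unname(ref$sequences[[sim$truth$taxon_id[i]]]))
  }
  expect_error(simulate_reads(ref, data.frame(sample_id = "s1",
                                              taxon_id = "nope",
                                              reads = 1L), spec),
               "unknown taxon")
})

test_that("reads at 2% substitution stay within the expected identity band", {
  spec <- sim_spec(n_orders = 1L, families_per_order = 1L,
                   genera_per_family = 1L, species_per_genus = 1L,
                   sub_rate = 0.02, ins_rate = 0, del_rate = 0,
                   low_q_fraction = 0, seed = 6)
  ref <- make_reference(spec)
  ab <- data.frame(sample_id = "s1", taxon_id = names(ref$sequences),
                   reads = 100L)
  sim <- simulate_reads(ref, ab, spec)
  idents <- vapply(sim$reads$sequence, pairwise_identity, numeric(1),
                   b = ref$sequences[[1]])
  expect_gt(mean(idents), 97)
  expect_lt(mean(idents), 99)
})

test_that("low-quality flagging aligns exactly with the quality filter", {
  spec <- sim_spec(n_orders = 1L, families_per_order = 1L,
                   genera_per_family = 1L, species_per_genus = 1L,
                   sub_rate = 0, ins_rate = 0, del_rate = 0,
                   low_q_fraction = 0.3, seed = 9)
  ref <- make_reference(spec)
  ab <- data.frame(sample_id = "s1", taxon_id = names(ref$sequences),
                   reads = 60L)
  sim <- simulate_reads(ref, ab, spec)
  expect_gt(sum(sim$truth$low_quality), 0)
  out <- filter_reads(sim$reads, filter_spec())
  flagged <- sim$truth$id[sim$truth$low_quality]
  expect_setequal(out$rejected$id, flagged)
  expect_true(all(out$rejected$reason == "quality"))
})

test_that("community matrices reflect the pool-overlap parameter", {
  # disjoint pools: every cross-habitat pair fully turns over
  spec0 <- sim_spec(pool_overlap = 0, pool_size = c(10L, 10L, 10L),
                    mean_richness = c(6, 6, 6), n_samples = c(3L, 3L, 3L),
                    seed = 14)
  cm0 <- simulate_community_matrix(spec0)
  expect_length(intersect(cm0$pools$grassland, cm0$pools$forest), 0L)
  pa <- presence_absence(cm0$counts)
  hab <- cm0$samples$habitat
  for (i in which(hab == "grassland")) {
    for (j in which(hab == "forest")) {
      expect_equal(beta_pair(pa[i, ] > 0, pa[j, ] > 0)[["beta_jac"]], 1)
    }
  }
  # full overlap with equal pool sizes: identical pools
  spec1 <- sim_spec(pool_overlap = 1, pool_size = c(10L, 10L, 10L),
                    seed = 15)
  cm1 <- simulate_community_matrix(spec1)
  expect_setequal(cm1$pools$grassland, cm1$pools$forest)

  expect_identical(simulate_community_matrix(spec0),
                   simulate_community_matrix(spec0))
})

test_that("habitat mean richness is recovered across seeds", {
  means <- c(12, 8, 6)
  rich <- matrix(NA_real_, 50, 3)
  for (s in 1:50) {
    spec <- sim_spec(mean_richness = means, n_samples = c(6L, 6L, 5L),
                     pool_size = c(30L, 25L, 20L), seed = s)
    cm <- simulate_community_matrix(spec)
    r <- rowSums(cm$counts > 0)
    rich[s, ] <- tapply(r, cm$samples$habitat, mean)[
      c("grassland", "shrubs", "forest")]
  }
  expect_true(all(abs(colMeans(rich) - means) <= 1))
})

test_that("the packaged incidence fixture matches its checksum and contents", {
  fx <- load_incidence_fixture()
  expect_equal(nrow(fx$table), 76L)
  expect_equal(unname(fx$n_samples), c(6L, 6L, 5L))
  expect_equal(fx$incidence["Acalles dubius", "grassland"], 1L)
  expect_equal(fx$reads["Acalles dubius", "grassland"], 39L)
  expect_equal(fx$incidence["Graphopsocus cruciatus", "forest"], 4L)
  expect_equal(fx$reads["Graphopsocus cruciatus", "forest"], 11633L)
  expect_true(all(fx$incidence <= rep(fx$n_samples, each = 76)))

  tampered <- tempfile(fileext = ".tsv")
  writeLines(c(readLines(system.file("extdata", "habitat_incidence.tsv",
                                     package = "swabdiv")), ""), tampered)
  expect_error(load_incidence_fixture(tampered), "checksum")
})
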