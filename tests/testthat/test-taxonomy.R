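make_lineage_map <- function() {
  data.frame(
    subject_id = c("ref1", "ref2", "ref3", "ref4", "ref5"),
    phylum = "Arthropoda",
    class = c("Insecta", "Insecta", "Insecta", "Insecta", "Collembola"),
    order = c("Coleoptera", "Coleoptera", "Coleoptera", "Diptera",
              "Entomobryomorpha"),
    family = c("Curculionidae", "Curculionidae", "Chrysomelidae",
               "Sciaridae", "Entomobryidae"),
    genus = c("Acalles", "Acalles", "Longitarsus", "Corynoptera",
              "Entomobrya"),
    species = c("Acalles dubius", "Acalles lemur", "Longitarsus luridus",
                "Corynoptera perpusilla", "Entomobrya nivalis"),
    stringsAsFactors = FALSE)
}

test_that("tabular hits are parsed with lineages; unresolved ids reported", {
  path <- tempfile()
  writeLines(c(
    "q1\tref1\t99.1\t215\t2\t0\t1\t215\t1\t215\t1e-50\t390\t100",
    "q1\tmissing\t97.0\t215\t6\t0\t1\t215\t1\t215\t1e-40\t350\t100"),
    path)
  hits <- parse_hits(path, make_lineage_map())
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$pident, 99.1)
  expect_equal(hits$qcovs, 100)
  expect_equal(hits$species, "Acalles dubius")
  unres <- attr(hits, "unresolved")
  expect_equal(unres$sseqid, "missing")

  empty <- parse_hits(tempfile(fileext = ".tsv"), make_lineage_map())
  expect_equal(nrow(empty), 0L)
})

test_that("coverage is computed from query lengths when qcovs is absent", {
  path <- tempfile()
  writeLines("q1\tref1\t99.0\t110\t1\t0\t1\t110\t1\t110\t1e-50\t200", path)
  expect_error(parse_hits(path, make_lineage_map()), "coverage")
  hits <- parse_hits(path, make_lineage_map(), query_lengths = c(q1 = 220L))
  expect_equal(hits$qcovs, 50)
})

test_that("hit filtering applies thresholds and keeps bitscore ties at the cutoff", {
  hits <- do.call(rbind, lapply(1:25, function(i) {
    hit_row("q1", paste0("s", i), pident = 95,
            bitscore = c(rep(400, 19), 390, 390, rep(380, 4))[i])
  }))
  out <- filter_hits(hits, top_n = 20)
  expect_equal(nrow(out), 21L)        # ranks 20 and 21 tied, both kept

  bad <- rbind(hit_row("q2", "s1", 99, 400, evalue = 1e-2),
               hit_row("q3", "s1", 70, 400),
               hit_row("q4", "s1", 99, 400, qcovs = 50))
  expect_equal(nrow(filter_hits(bad)), 0L)
})

test_that("lca is the longest common rank prefix", {
  l1 <- lineage("Arthropoda", "Insecta", "Coleoptera", "Curculionidae",
                "Acalles", "Acalles dubius")
  expect_equal(lca(list(l1)), l1)
  l2 <- lineage("Arthropoda", "Insecta", "Coleoptera", "Curculionidae",
                "Acalles", "Acalles lemur")
  expect_equal(rank_of(lca(list(l1, l2))), "genus")
  l3 <- lineage("Arthropoda", "Insecta", "Coleoptera", "Chrysomelidae",
                "Longitarsus", "Longitarsus luridus")
  expect_equal(rank_of(lca(list(l1, l3))), "order")
  expect_error(lca(list()), "at least one")
})

test_that("lca is idempotent and order-invariant (fuzz)", {
  set.seed(7)
  for (i in 1:200) {
    lins <- replicate(sample(1:4, 1), random_lineage(), simplify = FALSE)
    out <- lca(lins)
    expect_equal(lca(list(out, out)), out)
    expect_equal(lca(rev(lins)), out)
  }
})

test_that("assignments combine LCA with rank-specific identity thresholds", {
  # single high-identity hit: species level
  a1 <- assign_taxonomy(hit_row("q1", "ref1", 99.2, 400))
  expect_equal(a1$assigned_rank, "species")
  expect_equal(a1$species, "Acalles dubius")

  # two tied top hits, congeneric species: LCA truncates to genus
  h <- rbind(hit_row("q2", "ref1", 98.6, 400,
                     species = "Acalles dubius"),
             hit_row("q2", "ref2", 98.3, 400,
                     species = "Acalles lemur"))
  a2 <- assign_taxonomy(h)
  expect_equal(a2$assigned_rank, "genus")
  expect_equal(a2$genus, "Acalles")
  expect_true(is.na(a2$species))
  expect_equal(a2$top_identity, 98.6)
  expect_equal(a2$n_tied_top_hits, 2L)

  # 92% identity: species and genus stripped, family kept
  a3 <- assign_taxonomy(hit_row("q3", "ref1", 92, 400))
  expect_equal(a3$assigned_rank, "family")
  expect_equal(a3$family, "Curculionidae")
  expect_true(is.na(a3$genus))

  # 85%: below the family threshold, order survives
  a4 <- assign_taxonomy(hit_row("q4", "ref1", 85, 400))
  expect_equal(a4$assigned_rank, "order")
  expect_equal(a4$order, "Coleoptera")
})

test_that("raising the top identity never coarsens the assigned rank (fuzz)", {
  rank_depth <- c(higher = 0, order = 1, family = 2, genus = 3, species = 4)
  set.seed(13)
  for (i in 1:60) {
    n <- sample(1:3, 1)
    lins <- replicate(n, random_lineage(), simplify = FALSE)
    hits <- do.call(rbind, lapply(seq_len(n), function(j) {
      hit_row("q", paste0("s", j), pident = 0, bitscore = 400,
              phylum = lins[[j]][["phylum"]], class = lins[[j]][["class"]],
              order = lins[[j]][["order"]], family = lins[[j]][["family"]],
              genus = lins[[j]][["genus"]], species = lins[[j]][["species"]])
    }))
    depths <- vapply(seq(80, 100, by = 2), function(id) {
      hits$pident <- id
      rank_depth[[assign_taxonomy(hits)$assigned_rank]]
    }, numeric(1))
    expect_true(all(diff(depths) >= 0))
  }
})

test_that("non-target and over-general assignments are excluded", {
  asg <- rbind(
    cbind(data.frame(query_id = "q1"),
          as.data.frame(as.list(lineage("Arthropoda", "Insecta",
                                        "Coleoptera")))),
    cbind(data.frame(query_id = "q2"),
          as.data.frame(as.list(lineage("Chordata", "Mammalia",
                                        "Primates")))),
    cbind(data.frame(query_id = "q3"),
          as.data.frame(as.list(lineage("Arthropoda")))),  # class unresolved
    cbind(data.frame(query_id = "q4"),
          as.data.frame(as.list(lineage("Arthropoda", "Collembola",
                                        "Entomobryomorpha"))))
  )
  asg$assigned_rank <- c("order", "order", "higher", "order")
  out <- exclude_nontarget(asg)
  expect_setequal(out$kept$query_id, c("q1", "q4"))
  expect_equal(setNames(out$excluded$reason, out$excluded$query_id),
               c(q2 = "nontarget", q3 = "too_general"))
})

test_that("tabulation collapses identical lineages and conserves reads", {
  lin <- lineage("Arthropoda", "Insecta", "Coleoptera", "Curculionidae",
                 "Acalles", "Acalles dubius")
  asg <- do.call(rbind, lapply(c("q1", "q2", "q3"), function(q)
    cbind(data.frame(query_id = q), as.data.frame(as.list(lin)))))
  asg$species[3] <- "Acalles lemur"   # q3 is a different taxon
  asg$assigned_rank <- "species"
  counts <- data.frame(
    query_id = c("q1", "q2", "q1", "q3"),
    sample_id = c("s1", "s1", "s2", "s2"),
    reads = c(10L, 5L, 7L, 3L))
  comm <- tabulate_community(asg, counts)
  expect_equal(dim(comm$counts), c(2L, 2L))
  expect_equal(comm$counts["s1", "Acalles dubius"], 15L)  # q1+q2 collapsed
  expect_equal(comm$counts["s2", "Acalles dubius"], 7L)
  expect_equal(comm$counts["s2", "Acalles lemur"], 3L)
  expect_equal(sum(comm$counts), sum(counts$reads))       # conservation

  empty <- tabulate_community(asg[0, ], counts[0, ])
  expect_equal(ncol(empty$counts), 0L)
})

test_that("rank_of returns the deepest resolved rank", {
  expect_equal(rank_of(lineage("Arthropoda", "Insecta", "Coleoptera",
                               "Curculionidae", "Acalles",
                               "Acalles dubius")), "species")
  expect_equal(rank_of(lineage("Arthropoda", "Insecta", "Hymenoptera",
                               "Braconidae")), "family")
  expect_equal(rank_of(lineage("Arthropoda", "Insecta", "Coleoptera")),
               "order")
  expect_true(is.na(rank_of(lineage())))
})

test_that("a zero-error community is recovered exactly via the naive search", {
  spec <- sim_spec(n_orders = 2L, families_per_order = 2L,
                   genera_per_family = 1L, species_per_genus = 2L,
                   sub_rate = 0, ins_rate = 0, del_rate = 0,
                   low_q_fraction = 0, seed = 3)
  ref <- make_reference(spec)
  taxa <- names(ref$sequences)
  # one community member per family: taxa closer than the 97% clustering
  # threshold (congeners) cannot be split into separate clusters
  ab <- rbind(
    data.frame(sample_id = "s1", taxon_id = taxa[c(1, 3, 5)], reads = 6L),
    data.frame(sample_id = "s2", taxon_id = taxa[c(3, 7)], reads = 4L))
  sim <- simulate_reads(ref, ab, spec)
  cl <- cluster_reads(sim$reads, cluster_params(seed = 2))
  queries <- setNames(vapply(cl, `[[`, character(1), "consensus"),
                      paste0("cluster_", vapply(cl, `[[`, integer(1), "id")))
  lmap <- ref$lineages
  hits <- filter_hits(naive_search(queries, ref$sequences, lmap))
  asg <- exclude_nontarget(assign_taxonomy(hits))$kept
  qc <- do.call(rbind, lapply(cl, function(one) {
    samp <- sim$reads$sample_id[match(one$member_ids, sim$reads$id)]
    tb <- table(samp)
    data.frame(query_id = paste0("cluster_", one$id),
               sample_id = names(tb), reads = as.integer(tb))
  }))
  comm <- tabulate_community(asg, qc)
  truth_species <- ref$lineages$species[match(ab$taxon_id,
                                              ref$lineages$subject_id)]
  for (i in seq_len(nrow(ab))) {
    expect_equal(comm$counts[ab$sample_id[i], truth_species[i]],
                 ab$reads[i])
  }
  expect_equal(sum(comm$counts), sum(ab$reads))
})
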