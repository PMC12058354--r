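#' Simulation specification
#'
#' Parameters of the synthetic-data generators. The defaults emulate the
#' study conditions: ~215 bp mitochondrial 16S amplicons, three habitats
#' (grassland, shrubs, forest) sampled 6/6/5 times, a per-sample mean
#' richness gradient matching the observed per-sample means (14 / 8 / 7
#' taxa), habitat taxon pools sized like the observed per-habitat richness
#' (48 / 32 / 22) with low between-habitat overlap, and nanopore-like read
#' errors of about 2% split between substitutions and indels.
#'
#' @param n_orders,families_per_order,genera_per_family,species_per_genus
#'   Shape of the reference lineage tree.
#' @param amplicon_len Amplicon length in bases (default 215).
#' @param sub_rate,ins_rate,del_rate Per-base error rates in `[0, 0.2]`.
#' @param low_q_fraction Fraction of reads generated with mean quality
#'   below the Q12 filter threshold (default 0.1).
#' @param reads_per_taxon Default read depth per taxon per sample.
#' @param habitats Habitat labels.
#' @param n_samples Samples per habitat.
#' @param mean_richness Mean per-sample richness per habitat.
#' @param pool_size Taxon pool size per habitat.
#' @param pool_overlap Fraction of the smallest pool shared across all
#'   habitats (0 = disjoint pools, 1 = maximal sharing).
#' @param seed Integer seed; every generator is reproducible given the
#'   spec and seed.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_orders = 3L, families_per_order = 2L,
                     genera_per_family = 2L, species_per_genus = 2L,
                     amplicon_len = 215L,
                     sub_rate = 0.01, ins_rate = 0.005, del_rate = 0.005,
                     low_q_fraction = 0.1, reads_per_taxon = 20L,
                     habitats = c("grassland", "shrubs", "forest"),
                     n_samples = c(6L, 6L, 5L),
                     mean_richness = c(14, 8, 7),
                     pool_size = c(48L, 32L, 22L),
                     pool_overlap = 0.15, seed = 1L) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0 | rates > 0.2)) stop("error rates must lie in [0, 0.2]")
  if (amplicon_len < 50) stop("amplicon_len must be >= 50")
  if (length(n_samples) != length(habitats) ||
      length(mean_richness) != length(habitats) ||
      length(pool_size) != length(habitats)) {
    stop("n_samples, mean_richness and pool_size must match habitats")
  }
  if (pool_overlap < 0 || pool_overlap > 1) {
    stop("pool_overlap must lie in [0, 1]")
  }
  structure(list(n_orders = n_orders, families_per_order = families_per_order,
                 genera_per_family = genera_per_family,
                 species_per_genus = species_per_genus,
                 amplicon_len = as.integer(amplicon_len),
                 sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, low_q_fraction = low_q_fraction,
                 reads_per_taxon = as.integer(reads_per_taxon),
                 habitats = habitats,
                 n_samples = setNames(as.integer(n_samples), habitats),
                 mean_richness = setNames(mean_richness, habitats),
                 pool_size = setNames(as.integer(pool_size), habitats),
                 pool_overlap = pool_overlap, seed = as.integer(seed)),
            class = "sim_spec")
}

.bases <- c("A", "C", "G", "T")

.random_seq <- function(len) {
  paste(sample(.bases, len, replace = TRUE), collapse = "")
}

# Substitute exactly `k` positions, sampled uniformly; exact counts keep
# the divergence bands between taxonomic levels deterministic.
.mutate_subs <- function(seq, k) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), min(k, length(ch)))
  for (p in pos) ch[p] <- sample(setdiff(.bases, ch[p]), 1)
  paste(ch, collapse = "")
}

#' Generate a lineage-annotated reference
#'
#' Builds one reference sequence per species by seeded mutation along a
#' lineage tree: each order gets an independent random ancestor, family
#' ancestors diverge ~12% from their order ancestor, genus ancestors ~2.5%
#' from their family ancestor, and species ~0.5% from their genus
#' ancestor. These bands guarantee that congeneric species align above the
#' species threshold (>= 98% identity), confamilial genera fall between
#' the genus and family thresholds, and cross-family pairs fall below 90%;
#' the bands are verified with [pairwise_identity()] and the generator
#' rejection-samples until they hold (erroring if the requested tree makes
#' them infeasible).
#'
#' @param spec A [sim_spec()].
#' @return A list with `sequences` (named character vector, one per
#'   species), `lineages` (data frame: `subject_id` + the six ranks) and
#'   `spec`.
#' @export
make_reference <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  L <- spec$amplicon_len
  k_fam <- max(1L, round(0.12 * L))
  k_gen <- max(1L, round(0.025 * L))
  k_sp <- max(1L, round(0.005 * L))
  if (2 * k_sp / L > 0.02) {
    stop("infeasible divergence constraints: amplicon too short to keep ",
         "congeneric species above the species threshold")
  }
  with_seed(spec$seed, {
    for (attempt in 1:20) {
      seqs <- character(0)
      lins <- list()
      for (o in seq_len(spec$n_orders)) {
        ord_seq <- .random_seq(L)
        ord_name <- paste0("Ord", o)
        for (fa in seq_len(spec$families_per_order)) {
          fam_seq <- .mutate_subs(ord_seq, k_fam)
          fam_name <- paste0(ord_name, "fam", fa)
          for (g in seq_len(spec$genera_per_family)) {
            gen_seq <- .mutate_subs(fam_seq, k_gen)
            gen_name <- paste0(fam_name, "gen", g)
            for (s in seq_len(spec$species_per_genus)) {
              sp_seq <- .mutate_subs(gen_seq, k_sp)
              sp_name <- paste0(gen_name, " sp", s)
              id <- sprintf("SYN%04d", length(seqs) + 1L)
              seqs[[id]] <- sp_seq
              lins[[id]] <- data.frame(
                subject_id = id, phylum = "Arthropoda", class = "Insecta",
                order = ord_name, family = fam_name, genus = gen_name,
                species = sp_name, stringsAsFactors = FALSE)
            }
          }
        }
      }
      lineages <- do.call(rbind, lins)
      rownames(lineages) <- NULL
      if (.reference_bands_ok(seqs, lineages)) {
        return(list(sequences = seqs, lineages = lineages, spec = spec))
      }
    }
  })
  stop("infeasible divergence constraints: could not satisfy the identity ",
       "bands for the requested lineage tree")
}

# Within-genus pairs must stay >= 98% identity, cross-family pairs <= 90%.
.reference_bands_ok <- function(seqs, lineages) {
  n <- length(seqs)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      same_gen <- lineages$genus[i] == lineages$genus[j]
      same_fam <- lineages$family[i] == lineages$family[j]
      if (!same_gen && same_fam) next    # unconstrained band
      ident <- pairwise_identity(seqs[[i]], seqs[[j]])
      if (same_gen && ident < 98) return(FALSE)
      if (!same_fam && ident > 90) return(FALSE)
    }
  }
  TRUE
}

#' Write a reference as a lineage-annotated FASTA
#'
#' Headers follow the rank-prefixed token convention parsed by
#' [read_lineage_map()]:
#' `>SYN0001 phylum_Arthropoda;class_Insecta;order_...;species_...`.
#'
#' @param reference A reference from [make_reference()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  lin <- reference$lineages
  hdr <- vapply(seq_len(nrow(lin)), function(i) {
    tokens <- vapply(.ranks, function(r) {
      paste0(r, "_", gsub(" ", "_", lin[[r]][i]))
    }, character(1))
    paste0(">", lin$subject_id[i], " ", paste(tokens, collapse = ";"))
  }, character(1))
  writeLines(as.vector(rbind(hdr, unname(reference$sequences))), path)
  invisible(path)
}

# One read: apply per-base deletion, substitution, then insertions.
.corrupt_read <- function(template, sub, ins, del) {
  ch <- strsplit(template, "", fixed = TRUE)[[1]]
  ch <- ch[runif(length(ch)) >= del]
  if (length(ch) == 0L) ch <- sample(.bases, 1)
  subs <- runif(length(ch)) < sub
  for (p in which(subs)) ch[p] <- sample(setdiff(.bases, ch[p]), 1)
  ins_at <- which(runif(length(ch)) < ins)
  if (length(ins_at)) {
    out <- character(0)
    last <- 0L
    for (p in ins_at) {
      out <- c(out, ch[(last + 1L):p], sample(.bases, 1))
      last <- p
    }
    if (last < length(ch)) out <- c(out, ch[(last + 1L):length(ch)])
    ch <- out
  }
  paste(ch, collapse = "")
}

# Qualities drawn so that the error-domain mean Q lands on the requested
# side of the filter threshold; redrawn until it does.
.draw_qualities <- function(len, low_quality, threshold = 12) {
  for (i in 1:100) {
    q <- if (low_quality) round(rnorm(len, 8, 2)) else round(rnorm(len, 18, 3))
    q <- pmin(pmax(q, 2L), 40L)
    mq <- mean_qscore(as.integer(q))
    if (low_quality && mq < threshold) return(as.integer(q))
    if (!low_quality && mq >= threshold) return(as.integer(q))
  }
  stop("could not draw qualities on the requested side of the threshold")
}

#' Simulate nanopore-like amplicon reads with known ground truth
#'
#' Draws reads from reference templates according to a per-sample
#' abundance table, applying the spec's substitution/insertion/deletion
#' rates and per-base qualities. A `low_q_fraction` of reads is generated
#' with mean quality strictly below the Q12 filter threshold and flagged
#' in the ground truth, so quality filtering can be validated exactly.
#'
#' @param reference A reference from [make_reference()].
#' @param abundance A data frame with columns `sample_id`, `taxon_id`
#'   (reference subject id) and `reads`.
#' @param spec A [sim_spec()]; error rates, qualities and the seed come
#'   from here.
#' @return A list with `reads` (a read table as in [read_fastq()]) and
#'   `truth` (data frame: `id`, `sample_id`, `taxon_id`, `low_quality`).
#' @export
simulate_reads <- function(reference, abundance, spec = reference$spec) {
  stopifnot(inherits(spec, "sim_spec"))
  unknown <- setdiff(abundance$taxon_id, names(reference$sequences))
  if (length(unknown)) {
    stop("abundance references unknown taxon id(s): ",
         paste(unknown, collapse = ", "))
  }
  with_seed(spec$seed + 1L, {
    rows <- list()
    truth <- list()
    counter <- 0L
    for (i in seq_len(nrow(abundance))) {
      n <- abundance$reads[i]
      if (n == 0L) next
      template <- reference$sequences[[abundance$taxon_id[i]]]
      for (r in seq_len(n)) {
        counter <- counter + 1L
        id <- sprintf("read%06d", counter)
        seqr <- .corrupt_read(template, spec$sub_rate, spec$ins_rate,
                              spec$del_rate)
        lowq <- runif(1) < spec$low_q_fraction
        rows[[counter]] <- list(id = id, sequence = seqr,
                                qualities = .draw_qualities(nchar(seqr), lowq),
                                sample_id = abundance$sample_id[i])
        truth[[counter]] <- data.frame(
          id = id, sample_id = abundance$sample_id[i],
          taxon_id = abundance$taxon_id[i], low_quality = lowq)
      }
    }
    reads <- data.frame(
      id = vapply(rows, `[[`, character(1), "id"),
      sequence = vapply(rows, `[[`, character(1), "sequence"),
      sample_id = vapply(rows, `[[`, character(1), "sample_id"),
      stringsAsFactors = FALSE)
    reads$qualities <- lapply(rows, `[[`, "qualities")
    list(reads = reads[, c("id", "sequence", "qualities", "sample_id")],
         truth = do.call(rbind, truth))
  })
}

#' Simulate a habitat-structured site-by-taxon matrix
#'
#' Emulates the statistical structure of the field design: each habitat
#' has a taxon pool (sharing a common core controlled by `pool_overlap`),
#' per-sample richness is drawn around the habitat mean, the taxa present
#' in a sample are drawn from its habitat pool, and read counts follow a
#' log-normal abundance distribution. Sample metadata mirror the sampling
#' design: replicates 1-3 at two locations per habitat and an
#' hour-of-day covariate.
#'
#' @param spec A [sim_spec()].
#' @return A list with `counts` (samples x taxa matrix), `samples`
#'   (metadata data frame: `sample_id`, `habitat`, `replicate`,
#'   `location`, `time_of_day`) and `pools` (named list of habitat taxon
#'   pools).
#' @export
simulate_community_matrix <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed + 2L, {
    n_shared <- round(spec$pool_overlap * min(spec$pool_size))
    n_excl <- spec$pool_size - n_shared
    total <- n_shared + sum(n_excl)
    taxa <- sprintf("T%03d", seq_len(total))
    shared <- taxa[seq_len(n_shared)]
    pools <- list()
    offset <- n_shared
    for (h in spec$habitats) {
      pools[[h]] <- c(shared, taxa[offset + seq_len(n_excl[[h]])])
      offset <- offset + n_excl[[h]]
    }
    rows <- list()
    meta <- list()
    for (h in spec$habitats) {
      for (s in seq_len(spec$n_samples[[h]])) {
        sid <- paste0(substr(h, 1, 3), s)
        pool <- pools[[h]]
        r <- round(rnorm(1, spec$mean_richness[[h]], 2))
        r <- min(max(r, 1L), length(pool))
        present <- sample(pool, r)
        counts <- setNames(rep(0, total), taxa)
        counts[present] <- pmax(1, round(rlnorm(r, log(50), 1)))
        rows[[sid]] <- counts
        meta[[sid]] <- data.frame(
          sample_id = sid, habitat = h,
          replicate = ((s - 1L) %% 3L) + 1L,
          location = paste0(substr(h, 1, 3), "_loc", ((s - 1L) %/% 3L) + 1L),
          time_of_day = sample(9:16, 1))
      }
    }
    counts <- do.call(rbind, rows)
    samples <- do.call(rbind, meta)
    rownames(samples) <- NULL
    keep <- colSums(counts) > 0
    list(counts = counts[, keep, drop = FALSE], samples = samples,
         pools = pools)
  })
}

# md5 of the packaged incidence fixture; guards against silent edits.
.incidence_fixture_md5 <- "152286a609eaaca3c0865d639e4fa3db"

#' Load the packaged taxon-by-habitat incidence fixture
#'
#' Returns the packaged table of 76 hexapod taxa detected across three
#' habitats: incidence frequencies (number of samples in which each taxon
#' occurred; 6 grassland, 6 shrub and 5 forest samples) and per-habitat
#' read counts, with each taxon's family, order and deepest identified
#' rank. The file's checksum is verified on load.
#'
#' @param path Optional override of the packaged TSV (checksum still
#'   enforced unless `check = FALSE`).
#' @param check Verify the md5 checksum (default TRUE).
#' @return A list with `table` (the full data frame), `incidence`
#'   (76 x 3 integer matrix, habitats in columns), `reads` (76 x 3
#'   matrix), `n_samples` (named vector `c(grassland = 6, shrubs = 6,
#'   forest = 5)`) and `rank` (named character vector).
#' @export
load_incidence_fixture <- function(path = NULL, check = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "habitat_incidence.tsv",
                        package = "swabdiv", mustWork = TRUE)
  }
  if (check) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, .incidence_fixture_md5)) {
      stop("incidence fixture checksum mismatch: expected ", .incidence_fixture_md5,
           ", got ", md5)
    }
  }
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  habitats <- c("grassland", "shrubs", "forest")
  incidence <- as.matrix(tab[, paste0("nb_", habitats)])
  reads <- as.matrix(tab[, paste0("reads_", habitats)])
  dimnames(incidence) <- dimnames(reads) <- list(tab$taxon, habitats)
  list(table = tab, incidence = incidence, reads = reads,
       n_samples = c(grassland = 6L, shrubs = 6L, forest = 5L),
       rank = setNames(tab$rank, tab$taxon))
}
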