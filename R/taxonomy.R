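.hit_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
               "gapopen", "qstart", "qend", "sstart", "send",
               "evalue", "bitscore")

#' Parse similarity-search hits in tabular format
#'
#' Reads the 12-column tabular output convention (`outfmt 6`:
#' qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore), optionally followed by a 13th `qcovs` column with the
#' percent query coverage. When `qcovs` is absent, coverage is computed as
#' `(qend - qstart + 1) / query length * 100` from `query_lengths`;
#' lacking both is a format error, because the downstream filter requires
#' coverage.
#'
#' Subject ids are resolved against a lineage map; rows whose subject id
#' cannot be resolved are not silently dropped but collected in the
#' `unresolved` attribute of the result.
#'
#' @param path Path to the tabular hits file (no header).
#' @param lineage_map A data frame from [read_lineage_map()].
#' @param query_lengths Optional named vector of query sequence lengths,
#'   used to compute coverage when the file has no `qcovs` column.
#' @return A data frame of hits with the tabular columns, `qcovs`, and the
#'   six lineage ranks; unresolved rows are in `attr(, "unresolved")`.
#' @export
parse_hits <- function(path, lineage_map, query_lengths = NULL) {
  tab <- tryCatch(
    suppressWarnings(read.delim(path, header = FALSE,
                                stringsAsFactors = FALSE)),
    error = function(e) NULL
  )
  if (is.null(tab) || nrow(tab) == 0L) {
    out <- cbind(
      data.frame(matrix(nrow = 0, ncol = 13,
                        dimnames = list(NULL, c(.hit_cols, "qcovs")))),
      data.frame(matrix(character(0), nrow = 0, ncol = 6,
                        dimnames = list(NULL, .ranks)))
    )
    attr(out, "unresolved") <- out
    return(out)
  }
  if (ncol(tab) < 12L) {
    stop("hits file '", path, "' has ", ncol(tab),
         " columns; at least the 12 standard tabular columns are required")
  }
  names(tab)[1:12] <- .hit_cols
  if (ncol(tab) >= 13L) {
    names(tab)[13] <- "qcovs"
  } else if (!is.null(query_lengths)) {
    qlen <- query_lengths[tab$qseqid]
    if (anyNA(qlen)) {
      stop("query length missing for: ",
           paste(unique(tab$qseqid[is.na(qlen)]), collapse = ", "))
    }
    tab$qcovs <- 100 * (tab$qend - tab$qstart + 1) / qlen
  } else {
    stop("hits file '", path, "' lacks a qcovs column and no ",
         "query_lengths were supplied; cannot establish query coverage")
  }
  tab <- tab[, c(.hit_cols, "qcovs")]
  idx <- match(tab$sseqid, lineage_map$subject_id)
  resolved <- !is.na(idx)
  out <- cbind(tab[resolved, , drop = FALSE],
               lineage_map[idx[resolved], .ranks, drop = FALSE])
  rownames(out) <- NULL
  unres <- tab[!resolved, , drop = FALSE]
  rownames(unres) <- NULL
  attr(out, "unresolved") <- unres
  out
}

#' Filter hits on e-value, identity, coverage and rank
#'
#' Applies the hit-level retention thresholds: e-value at most `max_e`,
#' percent identity and query coverage at least `min_identity` /
#' `min_coverage`. Survivors are sorted by bitscore (descending) within
#' each query and at most `top_n` are retained, except that hits tied in
#' bitscore with the hit at the cutoff are all kept rather than broken
#' arbitrarily. Defaults reproduce the study settings (1e-3, 80, 80, 20).
#'
#' @param hits A hits data frame from [parse_hits()].
#' @param max_e Maximum e-value (default `1e-3`).
#' @param min_identity Minimum percent identity (default 80).
#' @param min_coverage Minimum percent query coverage (default 80).
#' @param top_n Hits retained per query (default 20).
#' @return The filtered hits data frame. Queries whose hits all fail are
#'   simply absent; compare query ids against the input to find them.
#' @export
filter_hits <- function(hits, max_e = 1e-3, min_identity = 80,
                        min_coverage = 80, top_n = 20L) {
  keep <- hits$evalue <= max_e & hits$pident >= min_identity &
    hits$qcovs >= min_coverage
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  out <- do.call(rbind, lapply(split(hits, hits$qseqid), function(h) {
    h <- h[order(-h$bitscore), , drop = FALSE]
    if (nrow(h) > top_n) {
      cutoff <- h$bitscore[top_n]
      h <- h[h$bitscore >= cutoff, , drop = FALSE]
    }
    h
  }))
  rownames(out) <- NULL
  out
}

#' Rank-specific identity thresholds
#'
#' Identity thresholds at which species-, genus- and family-level
#' assignments are accepted. Defaults reproduce the study settings
#' (98 / 96 / 90); ranks above family are retained whenever present, down
#' to the 80% identity floor applied by [filter_hits()].
#'
#' @param species_min,genus_min,family_min Percent identity thresholds;
#'   must satisfy `species_min >= genus_min >= family_min`.
#' @return An object of class `rank_thresholds`.
#' @export
rank_thresholds <- function(species_min = 98, genus_min = 96,
                            family_min = 90) {
  if (!(species_min >= genus_min && genus_min >= family_min)) {
    stop("need species_min >= genus_min >= family_min")
  }
  structure(list(species_min = species_min, genus_min = genus_min,
                 family_min = family_min), class = "rank_thresholds")
}

#' Threshold/LCA taxonomic assignment
#'
#' For each query the hits tied at the maximal bitscore are selected and
#' their lowest common ancestor ([lca()]) forms the candidate lineage; the
#' identity compared against the rank thresholds is the maximum identity
#' among those tied top hits. The candidate is then truncated: the species
#' is kept only when that identity reaches `species_min`, the genus only at
#' `genus_min`, the family only at `family_min`; ranks above family are
#' retained whenever the candidate resolves them.
#'
#' @param hits A filtered hits data frame (see [filter_hits()]).
#' @param thresholds A [rank_thresholds()] object.
#' @return A data frame with one row per query: `query_id`, the six rank
#'   columns of the assigned lineage, `assigned_rank` (`"species"`,
#'   `"genus"`, `"family"`, `"order"` or `"higher"`), `top_identity` and
#'   `n_tied_top_hits`.
#' @export
assign_taxonomy <- function(hits, thresholds = rank_thresholds()) {
  stopifnot(inherits(thresholds, "rank_thresholds"))
  if (nrow(hits) == 0L) {
    out <- data.frame(query_id = character(0))
    out[, .ranks] <- character(0)
    out$assigned_rank <- character(0)
    out$top_identity <- numeric(0)
    out$n_tied_top_hits <- integer(0)
    return(out)
  }
  rows <- lapply(split(hits, hits$qseqid), function(h) {
    top <- h[h$bitscore == max(h$bitscore), , drop = FALSE]
    cand <- lca(top)
    top_id <- max(top$pident)
    if (top_id < thresholds$species_min) cand[["species"]] <- NA_character_
    if (top_id < thresholds$genus_min) cand[["genus"]] <- NA_character_
    if (top_id < thresholds$family_min) cand[["family"]] <- NA_character_
    cand <- do.call(lineage, as.list(cand))  # re-establish prefix structure
    deepest <- rank_of(cand)
    bucket <- if (is.na(deepest)) "higher"
      else if (deepest %in% c("species", "genus", "family", "order")) deepest
      else "higher"
    cbind(data.frame(query_id = h$qseqid[1], stringsAsFactors = FALSE),
          as.data.frame(as.list(cand), stringsAsFactors = FALSE),
          data.frame(assigned_rank = bucket, top_identity = top_id,
                     n_tied_top_hits = nrow(top)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Split assignments into target-clade and non-target taxa
#'
#' Keeps assignments whose class places them inside the target clade; for
#' the default `"Hexapoda"` these are the classes Insecta, Collembola,
#' Diplura and Protura, so springtails are retained alongside true insects.
#' Assignments carrying no class (resolvable only above the clade, e.g. a
#' bare Metazoa) are excluded as too general; assignments with a class
#' outside the clade (e.g. Mammalia) are excluded as non-target.
#'
#' @param assignments An assignment data frame from [assign_taxonomy()].
#' @param target_clade Clade name; `"Hexapoda"` (default) activates the
#'   built-in hexapod class list, any other value is matched against the
#'   class label directly.
#' @return A list with elements `kept` and `excluded` (the latter with an
#'   extra `reason` column, `"nontarget"` or `"too_general"`).
#' @export
exclude_nontarget <- function(assignments, target_clade = "Hexapoda") {
  classes <- if (identical(target_clade, "Hexapoda")) .hexapod_classes
             else target_clade
  cls <- assignments$class
  keep <- !is.na(cls) & cls %in% classes
  excluded <- assignments[!keep, , drop = FALSE]
  excluded$reason <- ifelse(is.na(excluded$class), "too_general", "nontarget")
  kept <- assignments[keep, , drop = FALSE]
  rownames(kept) <- rownames(excluded) <- NULL
  list(kept = kept, excluded = excluded)
}

#' Tabulate assignments into a community matrix
#'
#' Queries (consensus sequences) with identical assigned lineages collapse
#' into a single taxon; read counts are summed per sample. The taxon label
#' is the deepest resolved rank's name.
#'
#' @param assignments An assignment data frame (typically the `kept` part
#'   of [exclude_nontarget()]).
#' @param query_counts A data frame with columns `query_id`, `sample_id`,
#'   `reads` giving per-sample read counts for each query.
#' @param samples Optional data frame of sample metadata with a
#'   `sample_id` column (habitat, replicate, time_of_day...); rows are
#'   aligned to the matrix rows.
#' @return An object of class `community_matrix`: a list with `counts`
#'   (samples x taxa integer matrix), `taxa` (data frame: `taxon`, the six
#'   ranks, `rank`) and `samples` (metadata data frame).
#' @export
tabulate_community <- function(assignments, query_counts, samples = NULL) {
  if (nrow(assignments) == 0L) {
    counts <- matrix(0L, 0L, 0L)
    return(structure(list(counts = counts,
                          taxa = data.frame(taxon = character(0)),
                          samples = samples %||%
                            data.frame(sample_id = character(0))),
                     class = "community_matrix"))
  }
  key <- apply(assignments[, .ranks], 1, paste, collapse = "|")
  label <- vapply(seq_len(nrow(assignments)), function(i) {
    lin <- setNames(as.character(assignments[i, .ranks]), .ranks)
    r <- rank_of(lin)
    if (is.na(r)) "unresolved" else lin[[r]]
  }, character(1))
  taxa_keys <- unique(key)
  first <- match(taxa_keys, key)
  taxa <- data.frame(taxon = label[first],
                     assignments[first, .ranks, drop = FALSE],
                     rank = assignments$assigned_rank[first],
                     stringsAsFactors = FALSE, row.names = NULL)

  qc <- query_counts[query_counts$query_id %in% assignments$query_id, ,
                     drop = FALSE]
  qc$taxon_key <- key[match(qc$query_id, assignments$query_id)]
  sample_ids <- if (!is.null(samples)) samples$sample_id
                else sort(unique(query_counts$sample_id))
  counts <- matrix(0L, nrow = length(sample_ids), ncol = length(taxa_keys),
                   dimnames = list(sample_ids, taxa$taxon))
  if (nrow(qc)) {
    agg <- aggregate(reads ~ sample_id + taxon_key, data = qc, FUN = sum)
    agg <- agg[agg$sample_id %in% sample_ids, , drop = FALSE]
    counts[cbind(agg$sample_id, taxa$taxon[match(agg$taxon_key, taxa_keys)])] <-
      as.integer(agg$reads)
  }
  structure(list(counts = counts, taxa = taxa,
                 samples = samples %||% data.frame(sample_id = sample_ids)),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("community matrix:", nrow(x$counts), "samples x", ncol(x$counts),
      "taxa;", sum(x$counts), "reads\n")
  if (nrow(x$taxa)) print(table(x$taxa$rank))
  invisible(x)
}

#' Presence/absence view of a community matrix
#'
#' @param x A `community_matrix` or a numeric samples-by-taxa matrix.
#' @return An integer 0/1 matrix of the same shape.
#' @export
presence_absence <- function(x) {
  m <- if (inherits(x, "community_matrix")) x$counts else x
  (m > 0) + 0L
}

#' Write a community matrix as TSV
#'
#' @param x A `community_matrix`.
#' @param path Output path (samples in rows, taxa in columns).
#' @return `path`, invisibly.
#' @export
write_community_tsv <- function(x, path) {
  out <- data.frame(sample_id = rownames(x$counts), x$counts,
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Exhaustive pairwise-identity search against a small reference
#'
#' A transparent, brute-force stand-in for an external similarity-search
#' tool, intended for small references (tens of sequences): every query is
#' globally aligned against every reference sequence and the results are
#' emitted in the same shape as [parse_hits()] so they flow through
#' [filter_hits()] and [assign_taxonomy()] unchanged. Global alignment
#' spans the whole query, so coverage is reported as 100 and the e-value as
#' 0; the bitscore surrogate is `pident * query length / 100` (monotone in
#' alignment quality), which preserves the tied-top-hit semantics the LCA
#' step relies on.
#'
#' @param queries Named character vector of query sequences.
#' @param reference Named character vector of reference sequences.
#' @param lineage_map A data frame from [read_lineage_map()] covering the
#'   reference ids.
#' @param min_identity Hits below this identity are not emitted
#'   (default 80).
#' @return A hits data frame compatible with [filter_hits()].
#' @export
naive_search <- function(queries, reference, lineage_map,
                         min_identity = 80) {
  queries <- .as_seqs(queries)
  reference <- .as_seqs(reference)
  rows <- lapply(seq_along(queries), function(i) {
    ident <- .identity_many(unname(reference), queries[[i]], min_identity)
    hit <- ident >= min_identity
    if (!any(hit)) return(NULL)
    qlen <- nchar(queries[[i]])
    data.frame(qseqid = names(queries)[i], sseqid = names(reference)[hit],
               pident = ident[hit], length = qlen, mismatch = NA_integer_,
               gapopen = NA_integer_, qstart = 1L, qend = qlen,
               sstart = 1L, send = nchar(reference[hit]),
               evalue = 0, bitscore = ident[hit] * qlen / 100,
               qcovs = 100, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  if (is.null(hits)) {
    hits <- data.frame(matrix(nrow = 0, ncol = 13,
                              dimnames = list(NULL, c(.hit_cols, "qcovs"))))
  }
  idx <- match(hits$sseqid, lineage_map$subject_id)
  if (anyNA(idx)) {
    stop("reference id(s) missing from lineage map: ",
         paste(unique(hits$sseqid[is.na(idx)]), collapse = ", "))
  }
  out <- cbind(hits, lineage_map[idx, .ranks, drop = FALSE])
  rownames(out) <- NULL
  out
}
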