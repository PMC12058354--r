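#' Clustering parameters
#'
#' Parameters of the batch-based greedy similarity clustering. Defaults
#' reproduce the study settings: reads are shuffled and processed in batches
#' of 1000, joined to a cluster when they match its seed at 97% identity,
#' and clusters are merged when their consensus sequences match at 98%.
#'
#' @param batch_size Number of reads per processing batch (default 1000).
#' @param within_sim Fractional identity required between a read and a
#'   cluster seed for membership (default 0.97).
#' @param merge_sim Fractional identity between consensus sequences at which
#'   clusters are merged (default 0.98). Must be >= `within_sim`.
#' @param seed Integer seed controlling the read shuffle; clustering is
#'   deterministic given the seed.
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(batch_size = 1000L, within_sim = 0.97,
                           merge_sim = 0.98, seed = 1L) {
  if (!(within_sim > 0 && within_sim <= merge_sim && merge_sim <= 1)) {
    stop("need 0 < within_sim <= merge_sim <= 1")
  }
  if (batch_size < 2) stop("batch_size must be >= 2")
  structure(list(batch_size = as.integer(batch_size),
                 within_sim = within_sim, merge_sim = merge_sim,
                 seed = as.integer(seed)),
            class = "cluster_params")
}

# Normalise read input to a named character vector of sequences.
.as_seqs <- function(reads) {
  if (is.data.frame(reads)) {
    check_reads(reads)
    return(setNames(reads$sequence, reads$id))
  }
  if (is.null(names(reads)) && length(reads) > 0) {
    names(reads) <- paste0("read", seq_along(reads))
  }
  reads
}

#' Greedy seeded clustering of reads
#'
#' Shuffles the reads with the given seed and processes them in batches of
#' `batch_size`. Each read is compared against the seeds of all existing
#' clusters (the seed is the cluster's first member); it joins the
#' best-matching seed whose identity is at least `within_sim`, otherwise it
#' founds a new cluster. Every read is assigned to exactly one cluster and
#' the result is deterministic given the seed. Consensus sequences are not
#' built here; see [build_consensus()] and [cluster_reads()].
#'
#' @param reads A read table (see [read_fastq()]) or a named character
#'   vector of sequences.
#' @param params A [cluster_params()] object.
#' @return A list of clusters; each cluster is a list with elements `id`,
#'   `seed_id`, `member_ids`, `members` (named character vector of member
#'   sequences) and `size`.
#' @export
cluster_batch <- function(reads, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  seqs <- .as_seqs(reads)
  if (length(seqs) == 0L) return(list())
  ord <- with_seed(params$seed, sample.int(length(seqs)))
  seqs <- seqs[ord]

  seed_seqs <- character(0)
  assignment <- integer(length(seqs))
  batches <- split(seq_along(seqs),
                   ceiling(seq_along(seqs) / params$batch_size))
  min_pct <- params$within_sim * 100
  for (batch in batches) {
    for (i in batch) {
      if (length(seed_seqs)) {
        ident <- .identity_many(seed_seqs, seqs[[i]], min_pct)
        best <- which.max(ident)
      }
      if (length(seed_seqs) && ident[best] >= min_pct) {
        assignment[i] <- best
      } else {
        seed_seqs <- c(seed_seqs, seqs[[i]])
        assignment[i] <- length(seed_seqs)
      }
    }
  }
  lapply(seq_along(seed_seqs), function(k) {
    members <- seqs[assignment == k]
    list(id = k, seed_id = names(members)[1],
         member_ids = names(members), members = members,
         size = length(members))
  })
}

# Medoid member: minimises summed alignment distance (100 - identity) to
# the other members.  Exhaustive for <= 200 members; for larger clusters
# both candidate set and reference set are subsampled (seeded by size so
# the choice stays deterministic).
.medoid <- function(members, max_exact = 200L) {
  n <- length(members)
  if (n <= 2L) return(members[[1]])
  if (n > max_exact) {
    idx <- with_seed(n, sample.int(n, max_exact))
    cand <- idx
    refs <- idx
  } else {
    cand <- seq_len(n)
    refs <- seq_len(n)
  }
  score <- vapply(cand, function(i) {
    sum(100 - .identity_many(unname(members[refs]), members[[i]]))
  }, numeric(1))
  members[[cand[which.min(score)]]]
}

#' Majority-vote consensus of cluster members
#'
#' Aligns every member globally to the cluster medoid (the member with the
#' smallest summed alignment distance to all members) and takes a
#' column-wise vote over the medoid's positions. Columns where gaps are the
#' strict plurality are deleted; ties between bases are broken
#' lexicographically (A < C < G < T); insertions relative to the medoid are
#' not represented. The result is deterministic.
#'
#' @param members Named character vector of member sequences (>= 1).
#' @return The consensus nucleotide string.
#' @export
build_consensus <- function(members) {
  members <- .as_seqs(members)
  if (length(members) == 0L) {
    stop("cannot build a consensus from an empty cluster")
  }
  if (length(members) == 1L) return(unname(members[[1]]))
  medoid <- .medoid(members)
  aln <- .align_global(unname(members), medoid)
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  L <- nchar(medoid)
  # per member: the character facing each medoid position
  cols <- vapply(seq_along(p), function(i) {
    pc <- strsplit(p[i], "", fixed = TRUE)[[1]]
    sc <- strsplit(s[i], "", fixed = TRUE)[[1]]
    pc[sc != "-"]
  }, character(L))
  if (L == 1L) cols <- matrix(cols, nrow = 1L)
  alphabet <- c("A", "C", "G", "T", "N")
  out <- apply(cols, 1, function(col) {
    counts <- table(factor(col, levels = c(alphabet, "-")))
    gaps <- counts[["-"]]
    bases <- counts[alphabet]
    top <- max(bases)
    if (gaps > top) return("")            # gap plurality: delete column
    alphabet[which(bases == top)[1]]      # lexicographic tie-break
  })
  paste(out, collapse = "")
}

#' Single-linkage merging of clusters by consensus identity
#'
#' Merges clusters whose consensus sequences match at `merge_sim` identity
#' or better, transitively (single linkage: A merges with C whenever both
#' match B, even if A and C themselves fall below the threshold). The
#' merged cluster's consensus is rebuilt from the union of the members, so
#' the no-remaining-pair guarantee applies to the consensi that were
#' compared, not to the rebuilt ones.
#'
#' @param clusters A list of clusters with `consensus` fields (see
#'   [cluster_reads()]); clusters lacking a consensus get one built.
#' @param params A [cluster_params()] object (`merge_sim` is used).
#' @return A list of merged clusters with rebuilt consensus sequences,
#'   renumbered 1..k in order of their smallest original id.
#' @export
merge_clusters <- function(clusters, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  k <- length(clusters)
  if (k == 0L) return(clusters)
  cons <- vapply(clusters, function(cl) {
    if (is.null(cl$consensus)) build_consensus(cl$members) else cl$consensus
  }, character(1))
  min_pct <- params$merge_sim * 100
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1L)) {
    ident <- .identity_many(cons[(i + 1L):k], cons[i], min_pct)
    for (j in which(ident >= min_pct)) {
      ri <- find(i); rj <- find(i + j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  groups <- split(seq_len(k), roots)
  merged <- lapply(groups, function(idx) {
    members <- do.call(c, lapply(clusters[idx], `[[`, "members"))
    consensus <- if (length(idx) == 1L) cons[idx] else build_consensus(members)
    list(id = min(vapply(clusters[idx], `[[`, integer(1), "id")),
         seed_id = clusters[[idx[1]]]$seed_id,
         member_ids = names(members), members = members,
         size = length(members), consensus = unname(consensus),
         merged_from = length(idx))
  })
  merged <- merged[order(vapply(merged, `[[`, integer(1), "id"))]
  for (i in seq_along(merged)) merged[[i]]$id <- i
  merged
}

#' Cluster reads end to end
#'
#' Convenience wrapper running [cluster_batch()], [build_consensus()] for
#' every cluster, and [merge_clusters()].
#'
#' @inheritParams cluster_batch
#' @param min_size Minimum cluster size retained in the output (default 1,
#'   i.e. no cluster is dropped; reads in smaller clusters are reported in
#'   the `unassigned` attribute rather than silently discarded).
#' @return A list of clusters, each with `id`, `member_ids`, `members`,
#'   `size` and `consensus`. Clusters below `min_size` are removed and
#'   their read ids recorded in `attr(, "unassigned")`.
#' @export
cluster_reads <- function(reads, params = cluster_params(), min_size = 1L) {
  clusters <- cluster_batch(reads, params)
  for (i in seq_along(clusters)) {
    clusters[[i]]$consensus <- build_consensus(clusters[[i]]$members)
  }
  clusters <- merge_clusters(clusters, params)
  small <- vapply(clusters, `[[`, integer(1), "size") < min_size
  unassigned <- unlist(lapply(clusters[small], `[[`, "member_ids"),
                       use.names = FALSE)
  clusters <- clusters[!small]
  for (i in seq_along(clusters)) clusters[[i]]$id <- i
  attr(clusters, "unassigned") <- unassigned %||% character(0)
  clusters
}

#' Cluster membership table
#'
#' @param clusters A list of clusters.
#' @return A data frame with columns `read_id`, `cluster_id`.
#' @export
membership_table <- function(clusters) {
  if (length(clusters) == 0L) {
    return(data.frame(read_id = character(0), cluster_id = integer(0)))
  }
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(read_id = cl$member_ids, cluster_id = cl$id)
  }))
}

#' Write consensus sequences as FASTA
#'
#' Headers carry the cluster id, size and, when a read table is supplied,
#' the per-sample composition of the cluster.
#'
#' @param clusters A list of clusters with consensus sequences.
#' @param path Output FASTA path.
#' @param reads Optional read table used to annotate sample composition.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(clusters, path, reads = NULL) {
  lines <- unlist(lapply(clusters, function(cl) {
    desc <- paste0("cluster_", cl$id, " size=", cl$size)
    if (!is.null(reads)) {
      samp <- table(reads$sample_id[match(cl$member_ids, reads$id)])
      desc <- paste0(desc, " samples=",
                     paste0(names(samp), ":", as.integer(samp), collapse = ","))
    }
    c(paste0(">", desc), cl$consensus)
  }))
  writeLines(lines %||% character(0), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
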