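# Independent oracles used to check the package's own implementations.
# Each one is deliberately brute-force and shares no code with R/.

# Needleman-Wunsch identity by dynamic programming: match +1, mismatch -1,
# gap -2 per column, end gaps charged.  Returns percent identity at one
# optimal alignment (matches / alignment columns).
nw_identity_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -2 * (0:n)
  S[1, ] <- -2 * (0:m)
  for (i in 1:n) {
    for (j in 1:m) {
      S[i + 1, j + 1] <- max(
        S[i, j] + if (A[i] == B[j]) 1 else -1,
        S[i, j + 1] - 2,
        S[i + 1, j] - 2
      )
    }
  }
  # traceback counting matches and columns
  i <- n; j <- m; matches <- 0; cols <- 0
  while (i > 0 || j > 0) {
    cols <- cols + 1
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (A[i] == B[j]) 1 else -1)) {
      if (A[i] == B[j]) matches <- matches + 1
      i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 2) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  100 * matches / cols
}

# Exhaustive sample-based rarefaction: average richness over all C(T, t)
# subsets of the incidence matrix rows.
rarefaction_subset_oracle <- function(incidence_matrix, t) {
  subsets <- utils::combn(nrow(incidence_matrix), t, simplify = FALSE)
  mean(vapply(subsets, function(idx) {
    sum(colSums(incidence_matrix[idx, , drop = FALSE]) > 0)
  }, numeric(1)))
}

# Incidence matrix with column sums Y over T rows (taxon i present in the
# first Y_i samples); exact rarefaction depends on Y only.
incidence_matrix_from_Y <- function(Y, T) {
  vapply(Y, function(y) c(rep(1L, y), rep(0L, T - y)), integer(T))
}

# Random lineage over a tiny taxonomy, truncated at a random depth.
random_lineage <- function() {
  labels <- list(phylum = "Arthropoda",
                 class = sample(c("Insecta", "Collembola"), 1),
                 order = sample(paste0("Ord", 1:3), 1),
                 family = sample(paste0("Fam", 1:4), 1),
                 genus = sample(paste0("Gen", 1:5), 1),
                 species = sample(paste0("sp", 1:6), 1))
  depth <- sample(1:6, 1)
  labels[seq_len(6) > depth] <- NA
  do.call(lineage, labels)
}

tmp_fastq <- function(records) {
  path <- tempfile(fileext = ".fastq")
  writeLines(unlist(records), path)
  path
}

# A tiny hits data frame builder with sensible defaults.
hit_row <- function(qseqid, sseqid, pident, bitscore, evalue = 1e-50,
                    qcovs = 100, phylum = "Arthropoda", class = "Insecta",
                    order = "Coleoptera", family = "Curculionidae",
                    genus = "Acalles", species = "Acalles dubius") {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = 215L, mismatch = 2L, gapopen = 0L, qstart = 1L,
             qend = 215L, sstart = 1L, send = 215L, evalue = evalue,
             bitscore = bitscore, qcovs = qcovs, phylum = phylum,
             class = class, order = order, family = family, genus = genus,
             species = species, stringsAsFactors = FALSE)
}
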