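# Global-alignment scoring used for all identity computations: match +1,
# mismatch -1, linear gap cost 2 per gap column, end gaps charged (true
# global alignment).  Identity is matches / alignment columns, with gap
# columns counted in the denominator.
.align_sub_mat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE, type = "DNA")
}

.align_global <- function(patterns, subject) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(patterns),
    subject = Biostrings::DNAString(subject),
    type = "global",
    substitutionMatrix = .align_sub_mat(),
    gapOpening = 0, gapExtension = 2
  )
}

.identity_from_aln <- function(aln) {
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  vapply(seq_along(p), function(i) {
    pc <- strsplit(p[i], "", fixed = TRUE)[[1]]
    sc <- strsplit(s[i], "", fixed = TRUE)[[1]]
    100 * sum(pc == sc & pc != "-") / length(pc)
  }, numeric(1))
}

#' Percent identity of two sequences under global alignment
#'
#' Aligns two nucleotide sequences end-to-end (Needleman-Wunsch; match +1,
#' mismatch -1, gap -2 per column, end gaps penalised) and returns the
#' percent identity computed as the number of identical aligned bases
#' divided by the total number of alignment columns, gap columns included.
#' This is the similarity criterion used both for read clustering and for
#' consensus-level cluster merging.
#'
#' @param a,b Nucleotide strings over `{A,C,G,T,N}`; both must be nonempty.
#' @return Percent identity in `[0, 100]`.
#' @examples
#' pairwise_identity("ACGT", "ACGT")  # 100
#' pairwise_identity("ACGT", "ACGA")  # 75
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) {
    stop("pairwise_identity requires two nonempty sequences")
  }
  .identity_from_aln(.align_global(a, b))
}

# Vectorised identity of many queries against one subject, with a cheap
# upper-bound prescreen: identity <= 100 * min(len) / max(len), so queries
# whose length ratio already rules out `min_identity` are skipped.
.identity_many <- function(queries, subject, min_identity = 0) {
  if (length(queries) == 0L) return(numeric(0))
  out <- rep(0, length(queries))
  nl <- nchar(queries)
  ns <- nchar(subject)
  bound <- 100 * pmin(nl, ns) / pmax(nl, ns)
  todo <- which(bound >= min_identity)
  if (length(todo)) {
    out[todo] <- .identity_from_aln(.align_global(queries[todo], subject))
  }
  out
}
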