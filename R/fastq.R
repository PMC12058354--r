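#' Read a FASTQ file into a read table
#'
#' Parses a four-line-per-record FASTQ file with Phred+33 quality encoding.
#' Reads are returned in file order as a data frame with one row per record
#' and the per-base qualities decoded to integer vectors.
#'
#' The parser is strict: a record whose quality string differs in length
#' from its sequence, a missing `@`/`+` separator, or a truncated final
#' record raise an error naming the offending record. Quality characters
#' below ASCII 33 are rejected rather than reinterpreted under another
#' offset.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @param sample_id Sample identifier attached to every read (default: the
#'   file name without extension).
#' @return A data frame with columns `id` (character), `sequence`
#'   (character, upper case), `qualities` (list of integer vectors) and
#'   `sample_id`.
#' @seealso [write_fastq()], [filter_reads()]
#' @export
read_fastq <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(fastq|fq)$", "", basename(path))
  }
  lines <- readLines(path)
  if (length(lines) == 0L) return(empty_reads(sample_id))
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ '", path, "': ", length(lines),
         " lines is not a multiple of 4 (truncated record at end of file)")
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  sep <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]

  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1], " in '", path,
         "': header does not start with '@' (", hdr[bad[1]], ")")
  }
  bad <- which(!startsWith(sep, "+"))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1], " (", hdr[bad[1]], ") in '",
         path, "': missing '+' separator line")
  }
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1], " (", hdr[bad[1]], ") in '",
         path, "': sequence and quality strings differ in length (",
         nchar(seqs[bad[1]]), " vs ", nchar(qual[bad[1]]), ")")
  }
  bad <- which(nchar(seqs) == 0L)
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1], " (", hdr[bad[1]], ") in '",
         path, "': empty sequence")
  }
  ids <- sub("^@", "", sub("\\s.*$", "", hdr))
  seqs <- toupper(seqs)
  bad <- which(grepl("[^ACGTN]", seqs))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1], " (", hdr[bad[1]], ") in '",
         path, "': sequence contains characters outside {A,C,G,T,N}")
  }
  quals <- lapply(qual, function(q) utf8ToInt(q) - 33L)
  low <- vapply(quals, function(q) any(q < 0L), logical(1))
  if (any(low)) {
    stop("malformed FASTQ record ", which(low)[1], " (", hdr[which(low)[1]],
         ") in '", path, "': quality character below ASCII 33; ",
         "only Phred+33 encoding is accepted")
  }
  reads <- data.frame(id = ids, sequence = seqs,
                      sample_id = sample_id, stringsAsFactors = FALSE)
  reads$qualities <- quals
  reads[, c("id", "sequence", "qualities", "sample_id")]
}

empty_reads <- function(sample_id = character(0)) {
  reads <- data.frame(id = character(0), sequence = character(0),
                      sample_id = character(0), stringsAsFactors = FALSE)
  reads$qualities <- list()
  reads[, c("id", "sequence", "qualities", "sample_id")]
}

#' Write a read table to FASTQ
#'
#' @param reads A read table as returned by [read_fastq()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  check_reads(reads)
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  qual <- vapply(reads$qualities,
                 function(q) intToUtf8(q + 33L), character(1))
  out <- as.vector(rbind(paste0("@", reads$id), reads$sequence, "+", qual))
  writeLines(out, path)
  invisible(path)
}

check_reads <- function(reads) {
  need <- c("id", "sequence", "qualities", "sample_id")
  if (!is.data.frame(reads) || !all(need %in% names(reads))) {
    stop("'reads' must be a data frame with columns ",
         paste(need, collapse = ", "))
  }
  if (nrow(reads) > 0L) {
    len_ok <- nchar(reads$sequence) ==
      vapply(reads$qualities, length, integer(1))
    if (!all(len_ok)) {
      stop("read(s) ", paste(reads$id[!len_ok], collapse = ", "),
           ": sequence and quality lengths differ")
    }
  }
  invisible(reads)
}

#' Mean quality score of a read
#'
#' Computes the average Phred quality of a read. The default follows the
#' nanopore convention for "average Q-score": each per-base Phred score is
#' converted to its error probability, the probabilities are averaged, and
#' the mean is converted back to the Phred scale,
#' \eqn{\bar Q = -10 \log_{10}(\frac{1}{L}\sum_i 10^{-q_i/10})}.
#' The arithmetic mean of the raw scores is available via
#' `method = "arithmetic"` but is not the default because it overstates the
#' quality of reads with a few very poor bases.
#'
#' @param q An integer vector of per-base Phred scores, or a read table as
#'   returned by [read_fastq()] (in which case a vector of mean scores, one
#'   per read, is returned).
#' @param method `"error"` (error-probability-domain average, default) or
#'   `"arithmetic"`.
#' @return Mean quality in Phred units.
#' @examples
#' mean_qscore(c(10L, 30L))   # 12.97, not 20
#' @export
mean_qscore <- function(q, method = c("error", "arithmetic")) {
  method <- match.arg(method)
  if (is.data.frame(q)) {
    check_reads(q)
    return(vapply(q$qualities, mean_qscore, numeric(1), method = method))
  }
  if (length(q) == 0L) stop("cannot compute the mean quality of an empty read")
  if (any(q < 0)) stop("Phred scores must be non-negative")
  if (method == "arithmetic") return(mean(q))
  -10 * log10(mean(10^(-q / 10)))
}

#' Read filtering specification
#'
#' Bundles the read-level retention thresholds: minimum mean quality and the
#' inclusive length window. Defaults reproduce the study settings (mean
#' Q >= 12, length within \[115, 315\] bases); both length bounds are kept.
#'
#' @param min_mean_q Minimum mean Phred quality (default 12).
#' @param min_len Minimum read length in bases, inclusive (default 115).
#' @param max_len Maximum read length in bases, inclusive (default 315).
#' @param q_method Averaging convention passed to [mean_qscore()].
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(min_mean_q = 12, min_len = 115L, max_len = 315L,
                        q_method = c("error", "arithmetic")) {
  q_method <- match.arg(q_method)
  if (min_mean_q < 0) stop("min_mean_q must be >= 0")
  if (min_len <= 0 || min_len > max_len) {
    stop("length bounds must satisfy 0 < min_len <= max_len")
  }
  structure(list(min_mean_q = min_mean_q, min_len = as.integer(min_len),
                 max_len = as.integer(max_len), q_method = q_method),
            class = "filter_spec")
}

#' Filter reads on length and mean quality
#'
#' Partitions a read table into kept and rejected reads. A read is kept when
#' its length lies in the inclusive window `[min_len, max_len]` and its mean
#' quality (see [mean_qscore()]) is at least `min_mean_q`. Every rejected
#' read carries a single reason; length violations are reported before
#' quality so that truncated primer artefacts are labelled as such even when
#' their quality is also poor.
#'
#' @param reads A read table as returned by [read_fastq()].
#' @param spec A [filter_spec()].
#' @return A list with elements `kept` (read table), `rejected` (read table
#'   with an extra `reason` column, one of `"too_short"`, `"too_long"`,
#'   `"quality"`) and `mean_q` (named vector of mean qualities of all input
#'   reads).
#' @export
filter_reads <- function(reads, spec = filter_spec()) {
  check_reads(reads)
  stopifnot(inherits(spec, "filter_spec"))
  if (nrow(reads) == 0L) {
    rej <- empty_reads()
    rej$reason <- character(0)
    return(list(kept = reads, rejected = rej, mean_q = numeric(0)))
  }
  len <- nchar(reads$sequence)
  mq <- mean_qscore(reads, method = spec$q_method)
  reason <- rep(NA_character_, nrow(reads))
  reason[mq < spec$min_mean_q] <- "quality"
  reason[len > spec$max_len] <- "too_long"
  reason[len < spec$min_len] <- "too_short"
  kept <- reads[is.na(reason), , drop = FALSE]
  rejected <- reads[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected,
       mean_q = setNames(mq, reads$id))
}

#' Write a rejection report
#'
#' @param rejected The `rejected` element of a [filter_reads()] result.
#' @param path Output TSV path (columns `read_id`, `reason`).
#' @return `path`, invisibly.
#' @export
write_rejections <- function(rejected, path) {
  out <- data.frame(read_id = rejected$id, reason = rejected$reason)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' A manifest maps per-sample FASTQ files to sample metadata. Required
#' columns: `file`, `sample_id`; the design columns `habitat`, `replicate`
#' and `time_of_day` are carried through to the diversity stage when
#' present.
#'
#' @param path Path to a tab-separated manifest.
#' @param base_dir Directory against which relative `file` entries are
#'   resolved (default: the manifest's directory).
#' @return A data frame of the manifest with `file` resolved.
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  man <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("file", "sample_id")
  miss <- setdiff(need, names(man))
  if (length(miss)) {
    stop("manifest '", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (anyDuplicated(man$sample_id)) {
    stop("manifest '", path, "' contains duplicated sample_id values")
  }
  rel <- !file.exists(man$file) & !grepl("^(/|[A-Za-z]:)", man$file)
  man$file[rel] <- file.path(base_dir, man$file[rel])
  man
}
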