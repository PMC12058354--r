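#' Construct a taxonomic lineage
#'
#' A lineage is a named character vector over the six ranks phylum, class,
#' order, family, genus, species. Ranks may be absent (`NA`), but only as a
#' suffix: once a rank is absent every finer rank must be absent too
#' (prefix structure). This is the invariant the lowest-common-ancestor
#' operation relies on.
#'
#' @param phylum,class,order,family,genus,species Rank labels or `NA`.
#' @return A named character vector of length 6.
#' @export
lineage <- function(phylum = NA, class = NA, order = NA, family = NA,
                    genus = NA, species = NA) {
  lin <- c(phylum = as.character(phylum), class = as.character(class),
           order = as.character(order), family = as.character(family),
           genus = as.character(genus), species = as.character(species))
  present <- !is.na(lin)
  if (any(present) && any(diff(present) > 0)) {
    stop("invalid lineage: rank '",
         .ranks[which(diff(present) > 0)[1] + 1L],
         "' is present below an absent rank")
  }
  lin
}

#' Parse a semicolon-delimited lineage string
#'
#' Accepts MIDORI2-style rank-prefixed tokens such as
#' `"phylum_Arthropoda_6656;class_Insecta_50557;order_Coleoptera_7041"`.
#' Tokens are `rank_Label` or `rank_Label_taxid`; tokens whose rank prefix
#' is not one of the six tracked ranks (e.g. `root`, `kingdom`) are
#' ignored. Underscores inside multi-word labels are preserved.
#'
#' @param x A lineage string.
#' @return A lineage (see [lineage()]).
#' @export
parse_lineage_string <- function(x) {
  tokens <- strsplit(trimws(x), ";", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  lin <- setNames(rep(NA_character_, 6L), .ranks)
  for (tok in tokens) {
    m <- regmatches(tok, regexec("^([a-zA-Z]+)_(.+)$", tok))[[1]]
    if (length(m) == 0L) next
    rank <- tolower(m[2])
    if (!rank %in% .ranks) next
    label <- sub("_[0-9]+$", "", m[3])        # strip trailing taxid
    label <- gsub("_", " ", label)
    lin[[rank]] <- label
  }
  do.call(lineage, as.list(lin))
}

#' Read a subject-id to lineage map
#'
#' Two on-disk formats are supported: a FASTA whose headers are
#' `>subject_id lineage-string` with the lineage in MIDORI2-style
#' rank-prefixed tokens (see [parse_lineage_string()]), or a two-column TSV
#' `subject_id <tab> lineage-string` (no header).
#'
#' @param path Path to the reference FASTA or TSV.
#' @return A data frame with columns `subject_id` and the six ranks.
#' @export
read_lineage_map <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, ">")) {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, ">")]
    ids <- sub("^>(\\S+).*$", "\\1", hdr)
    lin_str <- trimws(sub("^>\\S+\\s*", "", hdr))
  } else {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) {
      stop("lineage map '", path, "' must have two tab-separated columns")
    }
    ids <- as.character(tab[[1]])
    lin_str <- as.character(tab[[2]])
  }
  lins <- t(vapply(lin_str, parse_lineage_string,
                   setNames(character(6), .ranks)))
  out <- data.frame(subject_id = ids, lins, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(out) <- c("subject_id", .ranks)
  out
}

#' Lowest common ancestor of a set of lineages
#'
#' Returns the longest common rank prefix: ranks are compared from phylum
#' downwards and retained while all lineages agree on a non-absent label;
#' the first disagreement (or absence) truncates the result. `lca` is
#' idempotent and invariant to the order of its inputs.
#'
#' @param lineages A list of lineages, or a data frame / matrix with the
#'   six rank columns.
#' @return A lineage (see [lineage()]).
#' @export
lca <- function(lineages) {
  if (is.data.frame(lineages) || is.matrix(lineages)) {
    lineages <- lapply(seq_len(nrow(lineages)), function(i) {
      v <- unlist(lineages[i, .ranks, drop = TRUE])
      setNames(as.character(v), .ranks)
    })
  }
  if (length(lineages) == 0L) {
    stop("lca requires at least one lineage")
  }
  out <- setNames(rep(NA_character_, 6L), .ranks)
  for (rank in .ranks) {
    vals <- vapply(lineages, function(l) l[[rank]], character(1))
    if (anyNA(vals) || length(unique(vals)) != 1L) break
    out[[rank]] <- vals[1]
  }
  do.call(lineage, as.list(out))
}

#' Deepest resolved rank of a lineage
#'
#' @param lin A lineage (see [lineage()]).
#' @return One of `"phylum"`, `"class"`, `"order"`, `"family"`, `"genus"`,
#'   `"species"`, or `NA` when no rank is resolved.
#' @export
rank_of <- function(lin) {
  present <- which(!is.na(lin[.ranks]))
  if (length(present) == 0L) return(NA_character_)
  .ranks[max(present)]
}
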