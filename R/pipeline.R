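#' Pipeline run configuration
#'
#' A flat configuration object covering every stage. The defaults
#' reproduce the study's stated parameters end to end: mean Q >= 12,
#' length within \[115, 315\], clustering batches of 1000 at 97% identity
#' with consensus merging at 98%, hit filtering at e-value 1e-3 with 80%
#' identity and coverage keeping the top 20 hits, rank thresholds
#' 98/96/90, and the power-analysis design (3 groups, effect size 0.75,
#' alpha 0.05, power 0.8) with 999 permutations for PERMANOVA.
#'
#' @param manifest Path to the sample manifest TSV (see
#'   [read_manifest()]).
#' @param out_dir Output directory (created if absent).
#' @param stages Stages to run, in pipeline order; any subset of
#'   `c("filter", "cluster", "assign", "tabulate", "diversity")`.
#' @param min_mean_q,min_len,max_len,q_method Read filter settings
#'   ([filter_spec()]).
#' @param batch_size,within_sim,merge_sim,min_cluster_size Clustering
#'   settings ([cluster_params()]; `min_cluster_size` is the export
#'   filter).
#' @param hits_path Similarity-search hits in tabular format; when `NULL`
#'   the built-in [naive_search()] runs against `reference_path`.
#' @param reference_path Lineage-annotated reference FASTA.
#' @param lineage_map_path Lineage map (FASTA headers or 2-column TSV);
#'   defaults to `reference_path`.
#' @param max_e,min_identity,min_coverage,top_n Hit filter settings
#'   ([filter_hits()]).
#' @param species_min,genus_min,family_min Rank thresholds
#'   ([rank_thresholds()]).
#' @param target_clade Clade retained by [exclude_nontarget()].
#' @param k_groups,effect_size,alpha,target_power Power-analysis design
#'   ([anova_power_n()]).
#' @param n_permutations PERMANOVA permutations.
#' @param seed Master seed for all stochastic stages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(manifest = NULL, out_dir = "swabdiv_out",
                       stages = c("filter", "cluster", "assign",
                                  "tabulate", "diversity"),
                       min_mean_q = 12, min_len = 115L, max_len = 315L,
                       q_method = "error",
                       batch_size = 1000L, within_sim = 0.97,
                       merge_sim = 0.98, min_cluster_size = 1L,
                       hits_path = NULL, reference_path = NULL,
                       lineage_map_path = NULL,
                       max_e = 1e-3, min_identity = 80, min_coverage = 80,
                       top_n = 20L,
                       species_min = 98, genus_min = 96, family_min = 90,
                       target_clade = "Hexapoda",
                       k_groups = 3L, effect_size = 0.75, alpha = 0.05,
                       target_power = 0.8,
                       n_permutations = 999L, seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  # constructor validation happens up front, before any stage runs
  fspec <- filter_spec(min_mean_q, min_len, max_len, q_method)
  cparams <- cluster_params(batch_size, within_sim, merge_sim, seed)
  rthr <- rank_thresholds(species_min, genus_min, family_min)
  cfg <- list(manifest = manifest, out_dir = out_dir, stages = stages,
              filter = fspec, cluster = cparams,
              min_cluster_size = as.integer(min_cluster_size),
              hits_path = hits_path, reference_path = reference_path,
              lineage_map_path = lineage_map_path %||% reference_path,
              max_e = max_e, min_identity = min_identity,
              min_coverage = min_coverage, top_n = as.integer(top_n),
              thresholds = rthr, target_clade = target_clade,
              k_groups = as.integer(k_groups), effect_size = effect_size,
              alpha = alpha, target_power = target_power,
              n_permutations = as.integer(n_permutations),
              seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

#' Read a flat key = value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Keys are the
#' arguments of [run_config()]; values are coerced to the type of the
#' corresponding default. `stages` is a comma-separated list.
#'
#' @param path Path to the configuration file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  args <- list()
  for (pair in kv) {
    key <- pair[1]
    val <- paste(pair[-1], collapse = "=")
    if (key == "stages") {
      val <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    } else if (grepl("^-?[0-9.eE+-]+$", val) &&
               !is.na(suppressWarnings(as.numeric(val)))) {
      val <- as.numeric(val)
    } else if (val %in% c("NULL", "")) {
      val <- NULL
    }
    args[[key]] <- val
  }
  do.call(run_config, args)
}

.read_fasta_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Run the pipeline
#'
#' Executes the requested stages in order (filter, cluster, assign,
#' tabulate, diversity), writes each stage's outputs under
#' `config$out_dir` and returns (and writes as JSON) a run report with the
#' resolved configuration and per-stage counts. Runs are idempotent for a
#' fixed configuration and seed. When a stage fails, the partial outputs
#' of earlier stages are left on disk and the error names the stage.
#'
#' @param config A [run_config()] object.
#' @return The run report, invisibly: a list with `config`, per-stage
#'   summaries and the diversity results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = .config_as_list(config), stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return()
    t0 <- Sys.time()
    message("[", name, "] starting")
    res <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    report$stages[[name]] <<- res
    message("[", name, "] done in ",
            round(as.numeric(Sys.time() - t0, units = "secs"), 2), " s")
  }

  run_stage("filter", function() .stage_filter(config, state))
  run_stage("cluster", function() .stage_cluster(config, state))
  run_stage("assign", function() .stage_assign(config, state))
  run_stage("tabulate", function() .stage_tabulate(config, state))
  run_stage("diversity", function() .stage_diversity(config, state))

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

.config_as_list <- function(config) {
  flat <- list()
  for (nm in names(config)) {
    v <- config[[nm]]
    flat[[nm]] <- if (is.list(v)) unclass(v) else v
  }
  flat
}

.stage_filter <- function(config, state) {
  if (is.null(config$manifest)) stop("a manifest is required")
  man <- read_manifest(config$manifest)
  kept_all <- list()
  rejected <- 0L
  total <- 0L
  for (i in seq_len(nrow(man))) {
    reads <- read_fastq(man$file[i], sample_id = man$sample_id[i])
    total <- total + nrow(reads)
    fr <- filter_reads(reads, config$filter)
    rejected <- rejected + nrow(fr$rejected)
    write_fastq(fr$kept, file.path(config$out_dir,
                                   paste0(man$sample_id[i], ".filtered.fastq")))
    write_rejections(fr$rejected, file.path(
      config$out_dir, paste0(man$sample_id[i], ".rejected.tsv")))
    kept_all[[i]] <- fr$kept
  }
  state$manifest <- man
  state$reads <- do.call(rbind, kept_all)
  list(reads_in = total, reads_kept = nrow(state$reads),
       reads_rejected = rejected)
}

.stage_cluster <- function(config, state) {
  if (is.null(state$reads)) stop("no filtered reads; run the filter stage")
  clusters <- cluster_reads(state$reads, config$cluster,
                            min_size = config$min_cluster_size)
  write_consensus_fasta(clusters,
                        file.path(config$out_dir, "consensus.fasta"),
                        reads = state$reads)
  write.table(membership_table(clusters),
              file.path(config$out_dir, "membership.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  state$clusters <- clusters
  list(n_clusters = length(clusters),
       reads_clustered = sum(vapply(clusters, `[[`, integer(1), "size")),
       reads_unassigned = length(attr(clusters, "unassigned")))
}

.stage_assign <- function(config, state) {
  if (is.null(state$clusters)) stop("no clusters; run the cluster stage")
  queries <- setNames(
    vapply(state$clusters, `[[`, character(1), "consensus"),
    paste0("cluster_", vapply(state$clusters, `[[`, integer(1), "id")))
  if (is.null(config$lineage_map_path)) {
    stop("a lineage map (or reference FASTA) is required")
  }
  lmap <- read_lineage_map(config$lineage_map_path)
  if (!is.null(config$hits_path)) {
    hits <- parse_hits(config$hits_path, lmap,
                       query_lengths = nchar(queries))
  } else if (!is.null(config$reference_path)) {
    ref <- .read_fasta_seqs(config$reference_path)
    hits <- naive_search(queries, ref, lmap,
                         min_identity = config$min_identity)
  } else {
    stop("either hits_path or reference_path is required")
  }
  hits <- filter_hits(hits, config$max_e, config$min_identity,
                      config$min_coverage, config$top_n)
  assignments <- assign_taxonomy(hits, config$thresholds)
  split_tax <- exclude_nontarget(assignments, config$target_clade)
  out <- rbind(
    cbind(split_tax$kept, reason = "kept"),
    split_tax$excluded
  )
  write.table(out, file.path(config$out_dir, "assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  state$queries <- queries
  state$assignments <- split_tax$kept
  list(n_queries = length(queries),
       n_identified = length(unique(assignments$query_id)),
       n_kept = nrow(split_tax$kept),
       n_excluded = nrow(split_tax$excluded),
       by_rank = as.list(table(split_tax$kept$assigned_rank)))
}

.stage_tabulate <- function(config, state) {
  if (is.null(state$assignments)) stop("no assignments; run the assign stage")
  counts <- do.call(rbind, lapply(state$clusters, function(cl) {
    samp <- state$reads$sample_id[match(cl$member_ids, state$reads$id)]
    agg <- table(samp)
    data.frame(query_id = paste0("cluster_", cl$id),
               sample_id = names(agg), reads = as.integer(agg))
  }))
  comm <- tabulate_community(state$assignments, counts,
                             samples = state$manifest)
  write_community_tsv(comm, file.path(config$out_dir, "community.tsv"))
  state$community <- comm
  list(n_taxa = ncol(comm$counts), n_samples = nrow(comm$counts),
       reads_tabulated = sum(comm$counts))
}

.stage_diversity <- function(config, state) {
  if (is.null(state$community)) stop("no community matrix; run tabulate")
  res <- diversity_analysis(state$community$counts,
                            state$community$samples,
                            n_permutations = config$n_permutations,
                            seed = config$seed)
  res$power <- unclass(anova_power_n(config$k_groups, config$effect_size,
                                     config$alpha, config$target_power))
  jsonlite::write_json(.diversity_as_json(res),
                       file.path(config$out_dir, "diversity.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  state$diversity <- res
  .diversity_as_json(res)
}

.diversity_as_json <- function(res) {
  out <- list(power = res$power, alpha_diversity = res$alpha)
  out$accumulation <- lapply(res$accumulation, function(a) {
    if (is.null(a$fits)) {
      return(list(best_model = NULL, asymptote = NULL, aic = NULL))
    }
    list(best_model = a$best$model, asymptote = a$best$asymptote,
         aic = vapply(a$fits, `[[`, numeric(1), "aic"))
  })
  if (!is.null(res$permanova)) {
    out$permanova <- lapply(res$permanova, function(p) p$table)
  }
  if (!is.null(res$pcoa)) {
    out$pcoa <- lapply(res$pcoa, function(p)
      list(prop_explained = p$prop_explained))
  }
  out
}

#' Habitat-level diversity analysis of a community matrix
#'
#' The full statistical layer on a samples-by-taxa count matrix with
#' sample metadata: per-sample richness (q0) and evenness (q1 Hill
#' number); per-habitat exact rarefaction curves with all three
#' accumulation models fitted and the lowest-AIC model selected; the
#' Jaccard partition over all sample pairs; PERMANOVA of the available
#' design terms on both the full Jaccard dissimilarity and its turnover
#' component; and PCoA of both matrices.
#'
#' @param counts Samples-by-taxa count matrix.
#' @param samples Metadata data frame with `sample_id` and `habitat`
#'   columns; `replicate` and `time_of_day` are used as PERMANOVA terms
#'   when present with at least two levels.
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param seed Seed for the permutations.
#' @return A list with `alpha` (per-sample data frame), `accumulation`
#'   (per habitat: `curve`, `fits`, `best`), `beta` (the three `dist`
#'   objects), `permanova` (on `beta_jac` and `beta_jtu`) and `pcoa`.
#' @export
diversity_analysis <- function(counts, samples, n_permutations = 999L,
                               seed = 1L) {
  if (!all(c("sample_id", "habitat") %in% names(samples))) {
    stop("samples metadata needs 'sample_id' and 'habitat' columns")
  }
  counts <- counts[samples$sample_id, , drop = FALSE]
  alpha <- data.frame(
    sample_id = samples$sample_id, habitat = samples$habitat,
    richness = apply(counts, 1, function(x) sum(x > 0)),
    evenness_q1 = apply(counts, 1, function(x) {
      if (sum(x) == 0) NA_real_ else hill_number(x, q = 1)
    }))
  pa <- presence_absence(counts)
  accumulation <- lapply(split(seq_len(nrow(pa)), samples$habitat),
                         function(idx) {
    Y <- colSums(pa[idx, , drop = FALSE])
    curve <- accumulation_curve(Y, length(idx))
    if (nrow(curve) < 3L) {      # too few samples to fit any model
      return(list(curve = curve, fits = NULL, best = NULL))
    }
    fits <- fit_accumulation_all(curve)
    best <- tryCatch(select_best_model(fits), error = function(e) NULL)
    list(curve = curve, fits = fits, best = best)
  })
  beta <- beta_pair_matrix(counts)
  terms <- intersect(c("habitat", "replicate", "time_of_day"),
                     names(samples))
  terms <- terms[vapply(terms, function(tm) {
    length(unique(samples[[tm]])) >= 2L
  }, logical(1))]
  permanova_res <- pcoa_res <- NULL
  if (length(terms) && nrow(counts) >= 4L) {
    permanova_res <- lapply(beta[c("beta_jac", "beta_jtu")], permanova,
                            data = samples, terms = terms,
                            n_perm = n_permutations, seed = seed)
    pcoa_res <- lapply(beta[c("beta_jac", "beta_jtu")], pcoa)
  }
  list(alpha = alpha, accumulation = accumulation, beta = beta,
       permanova = permanova_res, pcoa = pcoa_res)
}

#' Fit the accumulation asymptote for one habitat
#'
#' Convenience wrapper: exact sample-based rarefaction of the incidence
#' frequencies followed by one accumulation-model fit.
#'
#' @inheritParams rarefy_exact
#' @param model Accumulation model (default `"asymptotic"`).
#' @return An `accum_fit`; its `asymptote` element is the estimated
#'   maximum taxon richness.
#' @export
accumulation_asymptote <- function(incidence, n_samples,
                                   model = "asymptotic") {
  fit_accumulation(accumulation_curve(incidence, n_samples), model = model)
}
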