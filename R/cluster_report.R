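# Genome-level RSCU clustering, per-genome analysis driver, and pipeline
# orchestration with TSV/Newick/JSON outputs.

#' Genome codon-usage profile
#'
#' Aggregates per-gene codon counts into a genome-level profile: the
#' 59-codon RSCU vector of the pooled counts and the per-genome means of the
#' gene-level indices (the summary-table analog).
#'
#' @param counts Genes x 64 codon count matrix.
#' @param table Per-gene index table ([gene_indices()]).
#' @param label Genome label.
#' @param code A [genetic_code()].
#' @return Object of class `"genome_profile"`: list with `label`, `rscu`
#'   (named 59-vector), `counts` (aggregated 64-vector), `means` (named
#'   numeric vector of index means).
#' @export
genome_profile <- function(counts, table, label, code = genetic_code()) {
  agg <- aggregate_counts(counts)
  idx_cols <- intersect(
    c("cai", "cbi", "fop", "gravy", "aromo", "enc",
      "gc1", "gc2", "gc3", "gc12", "gc3s", "gc"),
    names(table))
  means <- vapply(idx_cols, function(cl) mean(table[[cl]], na.rm = TRUE),
                  numeric(1))
  structure(
    list(label = label, rscu = rscu(agg, code), counts = agg,
         means = means),
    class = "genome_profile"
  )
}

#' Hierarchical clustering of genomes by RSCU
#'
#' Clusters genome-level 59-codon RSCU vectors with squared Euclidean
#' distance and between-groups average linkage (the codon-usage literature's
#' conventional SPSS-style pairing). Complete and Ward linkage are offered
#' as alternatives.
#'
#' @param profiles Named list of [genome_profile()] objects, or a genomes x
#'   codons RSCU matrix with genome rownames.
#' @param method Linkage: `"average"`, `"complete"` or `"ward.D2"` (Ward on
#'   unsquared distances).
#' @return An [stats::hclust] object.
#' @export
rscu_cluster <- function(profiles, method = c("average", "complete",
                                              "ward.D2")) {
  method <- match.arg(method)
  if (is.list(profiles) && !is.matrix(profiles)) {
    labels <- vapply(profiles, function(p) p$label, character(1))
    x <- do.call(rbind, lapply(profiles, `[[`, "rscu"))
    rownames(x) <- labels
  } else {
    x <- profiles
  }
  if (nrow(x) < 3L) stop("RSCU clustering needs at least 3 genomes")
  if (anyDuplicated(rownames(x))) {
    stop("duplicate genome labels: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]),
               collapse = ", "))
  }
  d <- stats::dist(x, method = "euclidean")
  if (method == "ward.D2") {
    stats::hclust(d, method = "ward.D2")
  } else {
    stats::hclust(d^2, method = method)
  }
}

#' Analyse one genome end to end
#'
#' Single-genome driver used by [run_pipeline()]: QC, codon counting,
#' reference weights and CAI, expression extremes, delta-RSCU and the
#' optimal-codon set, CBI/FOP against that set, neutrality fit, ENC-GC3s
#' curve, PR2 points, index correlations, correspondence analysis of
#' per-gene RSCU (axis 1 oriented by GC3s), codon-pair counts, context
#' residuals and the start/stop context report. The dependency order
#' follows the method: CAI (reference-based) defines the expression
#' extremes, which define the optimal set, which defines CBI and FOP.
#'
#' @param cds Data frame of coding sequences ([read_cds_fasta()] or
#'   [generate_genome()]`$cds`).
#' @param label Genome label.
#' @param policy A [qc_policy()].
#' @param reference List of arguments for [build_reference_weights()]
#'   (`selector`, `pattern`, `ids`, `fraction`).
#' @param extremes_fraction Fraction for [expression_extremes()].
#' @param delta_threshold,rscu_basis Passed to [delta_rscu()].
#' @param residual_threshold Passed to [context_residuals()].
#' @param n_axes Passed to [correspondence_analysis()].
#' @param code A [genetic_code()].
#' @return List of class `"genome_analysis"` with all per-genome results.
#' @export
analyze_genome <- function(cds, label = cds$genome[1L],
                           policy = qc_policy(),
                           reference = list(selector = "iterative"),
                           extremes_fraction = 0.05,
                           delta_threshold = 0.08,
                           rscu_basis = "high",
                           residual_threshold = 3,
                           n_axes = 4L,
                           code = genetic_code()) {
  qc <- qc_filter(cds, policy, code)
  if (nrow(qc$retained) == 0L) {
    stop("no genes passed QC for genome ", label)
  }
  counts <- codon_count_matrix(qc$retained, include_stop = FALSE, code)
  ref_args <- utils::modifyList(
    list(counts = counts, selector = "iterative",
         headers = if ("header" %in% names(qc$retained))
           qc$retained$header else qc$retained$id,
         code = code),
    reference)
  weights <- do.call(build_reference_weights, ref_args)
  tab <- gene_indices(counts, code, weights = weights, genome = label)
  extremes <- expression_extremes(tab, extremes_fraction)
  dr <- delta_rscu(
    counts[extremes$high, , drop = FALSE],
    counts[extremes$low, , drop = FALSE],
    aggregate_counts(counts),
    code, delta_threshold = delta_threshold, rscu_basis = rscu_basis)
  optimal <- optimal_codon_set(dr)
  if (length(optimal) > 0L) {
    # CBI/FOP need at most one optimal codon per family; when delta-RSCU
    # flags several, keep the family member with the largest delta.
    opt_dr <- dr[dr$optimal, , drop = FALSE]
    opt_dr <- opt_dr[order(opt_dr$aa, -opt_dr$delta_rscu), , drop = FALSE]
    optimal_one <- opt_dr$codon[!duplicated(opt_dr$aa)]
    tab$cbi <- apply(counts, 1L, cbi, optimal = optimal_one, code = code)
    tab$fop <- apply(counts, 1L, fop, optimal = optimal_one, code = code)
  }
  rm_mat <- rscu_matrix(counts, code)
  ca <- correspondence_analysis(rm_mat, n_axes = n_axes,
                                orient_by = tab$gc3s)
  ca_traits <- if (!isTRUE(ca$no_variation)) {
    axis_trait_correlations(ca, tab)
  } else NULL
  pairs <- count_codon_pairs(qc$retained, code)
  resid <- context_residuals(pairs, residual_threshold)
  context <- start_stop_context(pairs, resid, code = code)
  structure(
    list(
      label = label,
      qc = qc,
      counts = counts,
      weights = weights,
      table = tab,
      extremes = extremes,
      delta_rscu = dr,
      optimal = optimal,
      neutrality = neutrality_fit(tab),
      enc_curve = enc_curve_points(tab),
      pr2 = pr2_points(tab),
      correlations = index_correlations(tab),
      coa = ca,
      coa_traits = ca_traits,
      pairs = pairs,
      residuals = resid,
      context = context,
      pair_types = pair_types(pairs),
      profile = genome_profile(counts, tab, label, code)
    ),
    class = "genome_analysis"
  )
}

#' Run the full multi-genome pipeline
#'
#' Executes ingest, indices, mutation/selection diagnostics, correspondence
#' analysis, optimal-codon identification, codon-context analysis and the
#' cross-genome clusterings for every genome in the configuration, and
#' optionally writes all result tables (TSV), trees (Newick) and a run
#' manifest (JSON) to an output directory. A genome whose QC removes every
#' gene is recorded as failed in the manifest and the pipeline continues.
#' The core pipeline is deterministic; `seed` is recorded in the manifest
#' and applied for reproducibility of any stochastic extension.
#'
#' @param config A list or path to a YAML file. Recognised fields:
#'   `genomes` (named list: FASTA path per genome label - data frames of
#'   sequences may be supplied directly when calling from R), `qc` (args for
#'   [qc_policy()]), `reference`, `extremes_fraction`, `delta_threshold`,
#'   `rscu_basis`, `residual_threshold`, `n_axes`, `cluster_method`.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param seed Integer seed recorded in the manifest.
#' @return List of class `"cub_pipeline"`: `genomes` (per-genome
#'   `genome_analysis` objects), `failed` (named error messages),
#'   `codon_sets` ([compare_codon_sets()] result or `NULL`), `rscu_tree`,
#'   `context_tree` (hclust or `NULL`), `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = 1L) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$genomes))
  genomes <- config$genomes
  if (is.null(names(genomes)) || any(names(genomes) == "")) {
    stop("config$genomes must be a named list (one entry per genome)")
  }
  for (g in names(genomes)) {
    if (is.character(genomes[[g]]) && !file.exists(genomes[[g]])) {
      stop("FASTA path for genome '", g, "' does not exist: ",
           genomes[[g]])
    }
  }
  set.seed(seed)
  policy <- do.call(qc_policy, config$qc %||% list())
  code <- genetic_code()
  results <- list()
  failed <- character(0)
  for (g in names(genomes)) {
    res <- tryCatch({
      cds <- genomes[[g]]
      if (is.character(cds)) cds <- read_cds_fasta(cds, genome = g)
      analyze_genome(
        cds, label = g, policy = policy,
        reference = config$reference %||% list(selector = "iterative"),
        extremes_fraction = config$extremes_fraction %||% 0.05,
        delta_threshold = config$delta_threshold %||% 0.08,
        rscu_basis = config$rscu_basis %||% "high",
        residual_threshold = config$residual_threshold %||% 3,
        n_axes = config$n_axes %||% 4L,
        code = code)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[g] <- conditionMessage(res)
    } else {
      results[[g]] <- res
    }
  }
  codon_sets <- if (length(results) >= 2L) {
    compare_codon_sets(lapply(results, `[[`, "optimal"))
  } else NULL
  rscu_tree <- if (length(results) >= 3L) {
    rscu_cluster(lapply(results, `[[`, "profile"),
                 method = config$cluster_method %||% "average")
  } else NULL
  context_tree <- if (length(results) >= 3L) {
    cluster_contexts(lapply(results, `[[`, "residuals"))
  } else NULL
  manifest <- list(
    package = "cubtools",
    version = as.character(utils::packageVersion("cubtools")),
    seed = seed,
    genomes = names(results),
    failed = as.list(failed),
    parameters = list(
      extremes_fraction = config$extremes_fraction %||% 0.05,
      delta_threshold = config$delta_threshold %||% 0.08,
      rscu_basis = config$rscu_basis %||% "high",
      residual_threshold = config$residual_threshold %||% 3,
      n_axes = config$n_axes %||% 4L,
      cluster_method = config$cluster_method %||% "average",
      reference_selector =
        (config$reference %||% list(selector = "iterative"))$selector
    )
  )
  out <- structure(
    list(genomes = results, failed = failed, codon_sets = codon_sets,
         rscu_tree = rscu_tree, context_tree = context_tree,
         manifest = manifest),
    class = "cub_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.write_matrix_tsv <- function(m, path, label = "name") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- label
  .write_tsv(df, path)
}

#' Write all pipeline outputs
#'
#' Per genome: gene index table, QC report, delta-RSCU table, neutrality
#' fit, ENC curve points, PR2 points and quadrant summary, CA coordinates
#' and axis contributions, pair-count and residual matrices (RNA codon
#' labels), context report. Cross-genome: index-mean summary, optimal-codon
#' membership matrix, RSCU and context trees as Newick, and the JSON
#' manifest.
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summaries <- list()
  for (g in names(result$genomes)) {
    res <- result$genomes[[g]]
    gd <- file.path(out_dir, g)
    dir.create(gd, showWarnings = FALSE)
    .write_tsv(res$table, file.path(gd, "gene_indices.tsv"))
    write_qc_report(res$qc, file.path(gd, "qc_report.tsv"),
                    file.path(gd, "qc_summary.json"))
    .write_tsv(res$delta_rscu, file.path(gd, "delta_rscu.tsv"))
    .write_tsv(as.data.frame(unclass(res$neutrality)),
               file.path(gd, "neutrality.tsv"))
    .write_tsv(res$enc_curve, file.path(gd, "enc_gc3s.tsv"))
    .write_tsv(res$pr2$points, file.path(gd, "pr2_points.tsv"))
    .write_tsv(data.frame(quadrant = names(res$pr2$quadrants),
                          fraction = as.numeric(res$pr2$quadrants)),
               file.path(gd, "pr2_quadrants.tsv"))
    .write_matrix_tsv(res$correlations$r,
                      file.path(gd, "index_correlations_r.tsv"), "index")
    .write_matrix_tsv(res$correlations$p,
                      file.path(gd, "index_correlations_p.tsv"), "index")
    if (!isTRUE(res$coa$no_variation)) {
      .write_matrix_tsv(res$coa$gene_coords,
                        file.path(gd, "coa_gene_coords.tsv"), "id")
      .write_matrix_tsv(res$coa$codon_coords,
                        file.path(gd, "coa_codon_coords.tsv"), "codon")
      .write_tsv(data.frame(axis = seq_along(res$coa$contributions),
                            contribution_pct = res$coa$contributions),
                 file.path(gd, "coa_contributions.tsv"))
      if (!is.null(res$coa_traits)) {
        .write_tsv(res$coa_traits, file.path(gd, "coa_axis1_traits.tsv"))
      }
    }
    pm <- res$pairs
    dimnames(pm) <- lapply(dimnames(pm), codon_to_rna)
    .write_matrix_tsv(pm, file.path(gd, "pair_counts.tsv"), "codon5")
    rm_ <- res$residuals$residuals
    dimnames(rm_) <- lapply(dimnames(rm_), codon_to_rna)
    .write_matrix_tsv(round(rm_, 6), file.path(gd, "pair_residuals.tsv"),
                      "codon5")
    .write_tsv(res$context$start, file.path(gd, "context_start.tsv"))
    .write_tsv(res$context$stop, file.path(gd, "context_stop.tsv"))
    .write_tsv(res$context$top_pairs, file.path(gd, "context_top_pairs.tsv"))
    summaries[[g]] <- c(genome = g, res$profile$means,
                        n_genes = nrow(res$table),
                        pair_types = res$pair_types)
  }
  if (length(summaries) > 0L) {
    summary_df <- as.data.frame(do.call(rbind, summaries),
                                stringsAsFactors = FALSE)
    .write_tsv(summary_df, file.path(out_dir, "genome_summary.tsv"))
  }
  if (!is.null(result$codon_sets)) {
    .write_matrix_tsv(result$codon_sets$membership * 1L,
                      file.path(out_dir, "optimal_codon_membership.tsv"),
                      "codon")
  }
  if (!is.null(result$rscu_tree)) {
    write_dendrogram(result$rscu_tree, file.path(out_dir, "rscu_tree.nwk"))
  }
  if (!is.null(result$context_tree)) {
    write_dendrogram(result$context_tree,
                     file.path(out_dir, "context_tree.nwk"))
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
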