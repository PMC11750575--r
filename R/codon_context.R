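# Codon-pair context analysis: 64x64 adjacent-pair counts, contingency
# adjusted residuals, start/stop context reports, cross-genome clustering.

#' Count adjacent codon pairs
#'
#' Accumulates ordered (5' codon, 3' codon) pairs over all genes: a gene of
#' L codons (terminal stop included) contributes L - 1 pairs. Self-pairs
#' (e.g. CTG-CTG) count normally. Genes lacking a terminal stop still
#' contribute their sense-codon pairs and are flagged.
#'
#' @param cds Data frame of QC-passed sequences (columns `id`, `seq`).
#' @param code A [genetic_code()].
#' @return 64 x 64 integer matrix (rows = 5' codon, columns = 3' codon) with
#'   attributes `n_pairs` and `no_stop` (ids of genes without a terminal
#'   stop).
#' @export
count_codon_pairs <- function(cds, code = genetic_code()) {
  stopifnot(is.data.frame(cds), all(c("id", "seq") %in% names(cds)))
  cod_list <- lapply(cds$seq, split_codons)
  last <- vapply(cod_list, function(z) z[length(z)], character(1))
  no_stop <- cds$id[!(last %in% code$stop_codons)]
  from <- unlist(lapply(cod_list, function(z) z[-length(z)]),
                 use.names = FALSE)
  to <- unlist(lapply(cod_list, function(z) z[-1L]), use.names = FALSE)
  lv <- code$codons
  m <- table(factor(from, levels = lv), factor(to, levels = lv))
  m <- matrix(as.integer(m), 64L, 64L, dimnames = list(lv, lv))
  structure(m, n_pairs = sum(m), no_stop = no_stop)
}

#' Adjusted residuals of the codon-pair contingency table
#'
#' Treats the 64 x 64 pair-count matrix as a two-way contingency table:
#' expected count e_ij = r_i c_j / N from the marginals, adjusted residual
#' (o_ij - e_ij) / sqrt(e_ij (1 - r_i/N) (1 - c_j/N)). Under independence
#' the adjusted residuals are approximately standard normal, so cells with
#' residual beyond +/- `threshold` (default 3, roughly two-sided p 0.0027)
#' are called preferred or avoided codon pairs. Cells in a zero-marginal row
#' or column are undefined and returned as `NA`.
#'
#' @param pairs Matrix from [count_codon_pairs()].
#' @param threshold Residual magnitude for a preferred/avoided call.
#' @return Object of class `"context_residuals"`: list with `residuals`,
#'   `expected`, `observed` (64 x 64 matrices), `calls` (character matrix:
#'   `"preferred"`, `"avoided"`, `"neutral"`, `NA`), `threshold`, `n_pairs`.
#' @export
context_residuals <- function(pairs, threshold = 3) {
  stopifnot(is.matrix(pairs), nrow(pairs) == ncol(pairs))
  N <- sum(pairs)
  if (N < 1L) stop("empty pair matrix")
  if (N < 1000L) {
    warning("fewer than 1000 codon pairs; residuals will be noisy")
  }
  r <- rowSums(pairs)
  cc <- colSums(pairs)
  e <- outer(r, cc) / N
  denom <- sqrt(e * outer(1 - r / N, 1 - cc / N))
  resid <- (pairs - e) / denom
  undef <- outer(r == 0, cc == 0, "|") | denom == 0
  resid[undef] <- NA_real_
  calls <- matrix("neutral", nrow(pairs), ncol(pairs),
                  dimnames = dimnames(pairs))
  calls[resid > threshold] <- "preferred"
  calls[resid < -threshold] <- "avoided"
  calls[is.na(resid)] <- NA_character_
  structure(
    list(residuals = resid, expected = e, observed = pairs, calls = calls,
         threshold = threshold, n_pairs = N),
    class = "context_residuals"
  )
}

#' Start- and stop-codon context report
#'
#' Summarises the immediate sequence context of translation signals: for the
#' start codon ATG, the most-used 3' neighbour (by count) and most-avoided
#' 3' neighbour (most negative residual); for each stop codon (TAA, TAG,
#' TGA), the analogous 5' neighbours; plus the top-N most used codon pairs
#' genome-wide (sorted by count, ties by residual). Codon labels are
#' reported in the RNA alphabet (AUG, UAA, ...). Stop codons absent from the
#' genome are marked not applicable (`NA`).
#'
#' @param pairs Matrix from [count_codon_pairs()].
#' @param residuals A [context_residuals()] result for the same matrix.
#' @param top_n Number of top pairs to report.
#' @param code A [genetic_code()].
#' @return List with `start` (data frame for ATG), `stop` (data frame, one
#'   row per stop codon) and `top_pairs` (data frame: `pair`, `count`,
#'   `residual`).
#' @export
start_stop_context <- function(pairs, residuals, top_n = 10L,
                               code = genetic_code()) {
  res <- residuals$residuals
  pick_max <- function(counts) {
    if (all(counts == 0)) return(NA_character_)
    names(counts)[which.max(counts)]
  }
  pick_min_resid <- function(rv) {
    if (all(is.na(rv))) return(NA_character_)
    names(rv)[which.min(rv)]
  }
  start <- data.frame(
    codon = codon_to_rna("ATG"),
    most_used_3prime = codon_to_rna(pick_max(pairs["ATG", ])),
    most_avoided_3prime = codon_to_rna(pick_min_resid(res["ATG", ])),
    stringsAsFactors = FALSE
  )
  stop_rows <- lapply(code$stop_codons, function(sc) {
    if (sum(pairs[, sc]) == 0) {
      return(data.frame(codon = codon_to_rna(sc),
                        most_used_5prime = NA_character_,
                        most_avoided_5prime = NA_character_,
                        applicable = FALSE, stringsAsFactors = FALSE))
    }
    data.frame(
      codon = codon_to_rna(sc),
      most_used_5prime = codon_to_rna(pick_max(pairs[, sc])),
      most_avoided_5prime = codon_to_rna(pick_min_resid(res[, sc])),
      applicable = TRUE,
      stringsAsFactors = FALSE
    )
  })
  nz <- which(pairs > 0, arr.ind = TRUE)
  ord <- order(-pairs[nz], -res[nz])
  top <- nz[utils::head(ord, top_n), , drop = FALSE]
  top_pairs <- data.frame(
    pair = paste(codon_to_rna(rownames(pairs)[top[, 1L]]),
                 codon_to_rna(colnames(pairs)[top[, 2L]]), sep = "-"),
    count = pairs[top],
    residual = res[top],
    stringsAsFactors = FALSE
  )
  list(start = start, stop = do.call(rbind, stop_rows),
       top_pairs = top_pairs)
}

#' Count distinct codon-pair types
#'
#' Number of nonzero cells of the 64 x 64 pair matrix (of 4096 possible
#' ordered pairs).
#'
#' @param pairs Matrix from [count_codon_pairs()].
#' @return Integer count.
#' @export
pair_types <- function(pairs) {
  sum(pairs > 0)
}

#' Cluster genomes by codon-context pattern
#'
#' Flattens each genome's 64 x 64 adjusted-residual matrix to a
#' 4096-element vector (undefined cells as 0, so genomes with different
#' stop-codon repertoires stay comparable), computes pairwise distances
#' 1 - Pearson correlation, and clusters with average linkage.
#'
#' @param residual_list Named list (>= 3 genomes) of [context_residuals()]
#'   results or raw residual matrices.
#' @return An [stats::hclust] object; convert with [ape::as.phylo()] or
#'   serialise with [write_dendrogram()].
#' @export
cluster_contexts <- function(residual_list) {
  if (length(residual_list) < 3L) {
    stop("context clustering needs at least 3 genomes")
  }
  if (is.null(names(residual_list))) {
    stop("residual_list must be named by genome")
  }
  vecs <- vapply(residual_list, function(r) {
    m <- if (inherits(r, "context_residuals")) r$residuals else r
    v <- as.numeric(m)
    v[!is.finite(v)] <- 0
    v
  }, numeric(4096L))
  d <- 1 - stats::cor(vecs)
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Write a clustering as a Newick tree
#'
#' @param hc An [stats::hclust] object.
#' @param path Output file path.
#' @return Invisibly, the [ape::phylo] tree.
#' @export
write_dendrogram <- function(hc, path) {
  tree <- ape::as.phylo(hc)
  ape::write.tree(tree, file = path)
  invisible(tree)
}
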