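# Optimal-codon identification from CAI-defined expression extremes.

#' High- and low-expression gene sets by CAI
#'
#' Ranks genes by CAI (descending, ties broken deterministically by gene id)
#' and returns the top and bottom fraction as putative high- and
#' low-expression sets. Each set contains `max(1, floor(fraction * n))`
#' genes; the sets are disjoint for any `fraction <= 0.5`.
#'
#' @param table Per-gene index table with columns `id` and `cai`.
#' @param fraction Fraction of genes per set (default 0.05, i.e. top and
#'   bottom 5 percent).
#' @return Object of class `"expression_extremes"`: list with `high`, `low`
#'   (gene id vectors), `fraction`, `k`, `cai_cutoffs` (named: `high`,
#'   `low`), and `ties` (TRUE if ties at either cutoff were broken by id).
#' @export
expression_extremes <- function(table, fraction = 0.05) {
  stopifnot(all(c("id", "cai") %in% names(table)))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 0.5) {
    stop("fraction must lie in (0, 0.5]")
  }
  ok <- is.finite(table$cai)
  ids <- table$id[ok]
  cai <- table$cai[ok]
  n <- length(ids)
  if (n < 2L) stop("need at least 2 genes with CAI values")
  if (n < 20L) {
    warning("fewer than 20 genes; expression extremes will be unstable")
  }
  k <- max(1L, floor(fraction * n))
  ord <- order(-cai, ids)
  high <- ids[ord[seq_len(k)]]
  low <- ids[rev(ord)[seq_len(k)]]
  hi_cut <- cai[ord[k]]
  lo_cut <- cai[rev(ord)[k]]
  ties <- sum(cai == hi_cut) > 1L || sum(cai == lo_cut) > 1L
  if (length(unique(cai)) == 1L) {
    warning("all CAI values identical; sets chosen by gene id order")
  }
  structure(
    list(high = high, low = low, fraction = fraction, k = k,
         cai_cutoffs = c(high = hi_cut, low = lo_cut), ties = ties),
    class = "expression_extremes"
  )
}

#' Delta-RSCU table and optimal-codon classification
#'
#' Compares synonymous codon usage between the high- and low-expression gene
#' sets. For each of the 59 synonymous codons the RSCU of the high set, of
#' the low set, and of the whole genome is computed; delta-RSCU is high
#' minus low. Classification follows the standard thresholds:
#' \itemize{
#'   \item high-frequency codon: genome-wide RSCU > 1;
#'   \item optimal codon: delta-RSCU > 0.08 and RSCU > 1, where the RSCU
#'     threshold is evaluated on the high-expression set by default
#'     (`rscu_basis = "genome"` switches to genome-wide RSCU).
#' }
#' Both thresholds are strict inequalities.
#'
#' Set-level RSCU is computed from aggregated codon counts by default
#' (`method = "aggregate"`); `method = "mean"` instead averages per-gene
#' RSCU values, in which case `high` and `low` must be per-gene count
#' matrices.
#'
#' @param high,low Aggregated 64-codon count vectors for the two sets, or
#'   per-gene count matrices (rows = genes). Matrices are aggregated by
#'   summation unless `method = "mean"`.
#' @param genome Aggregated 64-codon count vector for the whole genome.
#' @param code A [genetic_code()].
#' @param delta_threshold Delta-RSCU threshold (default 0.08).
#' @param rscu_basis `"high"` or `"genome"`: which RSCU the `> 1` clause of
#'   the optimal-codon rule uses.
#' @param method `"aggregate"` or `"mean"` (see above).
#' @return Data frame with one row per synonymous codon: `codon`, `aa`,
#'   `rscu_high`, `rscu_low`, `rscu_genome`, `delta_rscu`,
#'   `high_frequency`, `optimal`.
#' @export
delta_rscu <- function(high, low, genome, code = genetic_code(),
                       delta_threshold = 0.08,
                       rscu_basis = c("high", "genome"),
                       method = c("aggregate", "mean")) {
  rscu_basis <- match.arg(rscu_basis)
  method <- match.arg(method)
  set_rscu <- function(x, label) {
    if (is.matrix(x)) {
      if (nrow(x) == 0L) stop("empty ", label, " gene set")
      if (method == "mean") {
        return(colMeans(rscu_matrix(x, code)))
      }
      x <- aggregate_counts(x)
    }
    if (sum(x) == 0) stop("empty ", label, " gene set")
    rscu(x, code)
  }
  r_high <- set_rscu(high, "high-expression")
  r_low <- set_rscu(low, "low-expression")
  r_gen <- rscu(genome, code)
  codons <- code$synonymous_codons
  basis <- if (rscu_basis == "high") r_high[codons] else r_gen[codons]
  d <- r_high[codons] - r_low[codons]
  data.frame(
    codon = codons,
    aa = unname(code$codon_aa[codons]),
    rscu_high = unname(r_high[codons]),
    rscu_low = unname(r_low[codons]),
    rscu_genome = unname(r_gen[codons]),
    delta_rscu = unname(d),
    high_frequency = unname(r_gen[codons] > 1),
    optimal = unname(d > delta_threshold & basis > 1),
    stringsAsFactors = FALSE
  )
}

#' Extract the optimal-codon set from a delta-RSCU table
#'
#' @param dr A [delta_rscu()] table.
#' @return Character vector of optimal codons.
#' @export
optimal_codon_set <- function(dr) {
  dr$codon[dr$optimal]
}

#' Compare codon sets across genomes
#'
#' Builds a codon x genome presence/absence matrix from per-genome codon
#' sets (optimal or high-frequency codons), the set of codons shared by all
#' genomes, and the ending-base tally (A/T- vs G/C-ending) of the shared
#' codons.
#'
#' @param sets Named list (one element per genome) of codon character
#'   vectors.
#' @return List with `membership` (logical matrix, codons x genomes),
#'   `shared` (codons present in every genome), `n_shared`, and
#'   `shared_ending` (named counts `AT` and `GC`).
#' @export
compare_codon_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L) {
    stop("need codon sets from at least 2 genomes")
  }
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must be a uniquely named list (one element per genome)")
  }
  codons <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) codons %in% s,
                       logical(length(codons)))
  if (length(codons) == 1L) {
    membership <- matrix(membership, nrow = 1L,
                         dimnames = list(codons, names(sets)))
  } else {
    rownames(membership) <- codons
  }
  shared <- codons[rowSums(membership) == length(sets)]
  ending <- substring(shared, 3L, 3L)
  list(
    membership = membership,
    shared = shared,
    n_shared = length(shared),
    shared_ending = c(AT = sum(ending %in% c("A", "T")),
                      GC = sum(ending %in% c("G", "C")))
  )
}
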