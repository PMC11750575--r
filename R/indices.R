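# Composition and codon-usage-bias indices. All functions take a named
# 64-codon count vector (stop counts are ignored where the index is defined
# on sense codons only) and a genetic_code object.

.codon_bases <- function(code) {
  do.call(rbind, strsplit(code$codons, ""))
}

#' Nucleotide composition of a gene or gene set
#'
#' Position-wise G+C fractions over sense codons (GC1, GC2, GC3, their mean
#' GC12, and overall GC), the third-position base counts A3/U3/G3/C3 used by
#' the PR2-bias plot, and GC3s: G+C at third positions restricted to codons
#' of synonymous families (degeneracy >= 2, i.e. excluding Met, Trp and
#' stops).
#'
#' @param counts Named codon count vector (as from [count_codons()] or
#'   [aggregate_counts()]).
#' @param code A [genetic_code()].
#'
#' @return Named list: `gc1`, `gc2`, `gc3`, `gc12`, `gc3s`, `gc` (fractions
#'   in \[0,1\]), `a3`, `u3`, `g3`, `c3` (integer counts over sense codons)
#'   and `n_sense` (number of sense codons).
#' @export
composition <- function(counts, code = genetic_code()) {
  x <- counts[code$sense_codons]
  n <- sum(x)
  if (n == 0) stop("gene has zero sense codons")
  b <- do.call(rbind, strsplit(code$sense_codons, ""))
  is_gc <- function(v) v %in% c("G", "C")
  gc1 <- sum(x[is_gc(b[, 1L])]) / n
  gc2 <- sum(x[is_gc(b[, 2L])]) / n
  gc3 <- sum(x[is_gc(b[, 3L])]) / n
  syn <- code$sense_codons %in% code$synonymous_codons
  n_syn <- sum(x[syn])
  gc3s <- if (n_syn > 0) sum(x[syn & is_gc(b[, 3L])]) / n_syn else NA_real_
  third <- b[, 3L]
  list(
    gc1 = gc1, gc2 = gc2, gc3 = gc3, gc12 = (gc1 + gc2) / 2,
    gc3s = gc3s,
    gc = (gc1 + gc2 + gc3) / 3,
    a3 = as.integer(sum(x[third == "A"])),
    u3 = as.integer(sum(x[third == "T"])),
    g3 = as.integer(sum(x[third == "G"])),
    c3 = as.integer(sum(x[third == "C"])),
    n_sense = as.integer(n)
  )
}

#' Relative synonymous codon usage (RSCU)
#'
#' For codon j of a synonymous family with total count n and family size k,
#' RSCU = x_j / (n / k): the observed count over the count expected if all
#' family members were used equally. RSCU = 1 for every codon under uniform
#' usage; values sum to the family size within each used family. Families
#' with zero total usage get RSCU 0 for all members and are flagged absent.
#' Met and Trp (single-codon families) are excluded, giving 59 values.
#'
#' @inheritParams composition
#' @return Named numeric vector over the 59 synonymous codons, with
#'   attribute `absent_families` (amino acids with zero usage).
#' @export
rscu <- function(counts, code = genetic_code()) {
  out <- stats::setNames(numeric(length(code$synonymous_codons)),
                         code$synonymous_codons)
  absent <- character(0)
  for (aa in names(code$synonymous_families)) {
    fam <- code$synonymous_families[[aa]]
    x <- as.numeric(counts[fam])
    tot <- sum(x)
    if (tot == 0) {
      absent <- c(absent, aa)
    } else {
      out[fam] <- x / (tot / length(fam))
    }
  }
  attr(out, "absent_families") <- absent
  out
}

#' Per-gene RSCU matrix
#'
#' @param counts Genes x 64 codon count matrix.
#' @param code A [genetic_code()].
#' @return Genes x 59 numeric matrix of RSCU values.
#' @export
rscu_matrix <- function(counts, code = genetic_code()) {
  out <- matrix(0, nrow(counts), length(code$synonymous_codons),
                dimnames = list(rownames(counts), code$synonymous_codons))
  for (fam in code$synonymous_families) {
    x <- counts[, fam, drop = FALSE]
    expc <- rowSums(x) / length(fam)
    r <- x / expc
    r[expc == 0, ] <- 0
    out[, fam] <- r
  }
  out
}

#' Relative-adaptiveness weights from a reference gene set
#'
#' Builds CAI weights from a set of (putatively) highly expressed genes:
#' codon RSCU over the aggregated reference counts, divided by the maximum
#' RSCU within each synonymous family, so the most-used family member has
#' w = 1. Codons unused in the reference receive a small pseudo-weight
#' (CodonW's convention) so CAI stays finite.
#'
#' Three reference selectors are provided, because annotated highly
#' expressed gene sets are often unavailable:
#' \describe{
#'   \item{annotation}{genes whose FASTA header matches `pattern`
#'     (default: ribosomal proteins).}
#'   \item{list}{an explicit vector of gene ids.}
#'   \item{iterative}{two-pass bootstrap: provisional weights from
#'     genome-wide usage give a provisional CAI; the top `fraction` of genes
#'     by that CAI becomes the reference.}
#' }
#'
#' @param counts Genes x 64 codon count matrix (rownames = gene ids).
#' @param selector `"annotation"`, `"list"` or `"iterative"`.
#' @param headers Character vector of FASTA headers aligned with the rows of
#'   `counts` (needed for `selector = "annotation"`).
#' @param pattern Regex matched case-insensitively against `headers`.
#' @param ids Gene ids for `selector = "list"`.
#' @param fraction Top fraction used by the iterative selector.
#' @param pseudo_weight Weight assigned to reference-unused codons.
#' @param code A [genetic_code()].
#'
#' @return Named numeric vector of weights over the 59 synonymous codons,
#'   all in (0, 1], with attributes `provenance` and `reference_ids`.
#' @export
build_reference_weights <- function(counts,
                                    selector = c("annotation", "list",
                                                 "iterative"),
                                    headers = NULL,
                                    pattern = "ribosomal[ _-]?protein",
                                    ids = NULL,
                                    fraction = 0.05,
                                    pseudo_weight = 0.01,
                                    code = genetic_code()) {
  selector <- match.arg(selector)
  gene_ids <- rownames(counts)
  ref <- switch(selector,
    annotation = {
      if (is.null(headers)) headers <- gene_ids
      gene_ids[grepl(pattern, headers, ignore.case = TRUE)]
    },
    list = intersect(ids, gene_ids),
    iterative = {
      w0 <- .weights_from_counts(aggregate_counts(counts), pseudo_weight,
                                 code)
      cai0 <- cai_per_gene(counts, w0, code)
      k <- max(1L, floor(fraction * length(cai0)))
      gene_ids[order(-cai0, gene_ids)][seq_len(k)]
    }
  )
  if (length(ref) == 0L) {
    stop("empty reference gene set for selector '", selector,
         "'; supply explicit gene ids (selector = \"list\") or a matching ",
         "annotation pattern")
  }
  w <- .weights_from_counts(aggregate_counts(counts[ref, , drop = FALSE]),
                            pseudo_weight, code)
  attr(w, "provenance") <- selector
  attr(w, "reference_ids") <- ref
  w
}

.weights_from_counts <- function(agg, pseudo_weight, code) {
  r <- rscu(agg, code)
  w <- stats::setNames(numeric(length(r)), names(r))
  for (fam in code$synonymous_families) {
    m <- max(r[fam])
    w[fam] <- if (m > 0) r[fam] / m else 0
  }
  w[w == 0] <- pseudo_weight
  w
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of the relative-adaptiveness weights of a gene's codons,
#' excluding Met, Trp and stop codons: exp(mean of log w). CAI ranges over
#' (0, 1]; 1 means every codon is the preferred codon of the reference set.
#'
#' @param counts Named 64-codon count vector.
#' @param weights Weights from [build_reference_weights()].
#' @param code A [genetic_code()].
#' @return CAI in (0, 1].
#' @export
cai <- function(counts, weights, code = genetic_code()) {
  x <- as.numeric(counts[names(weights)])
  L <- sum(x)
  if (L == 0) stop("gene has no scorable codons for CAI")
  exp(sum(x * log(weights)) / L)
}

#' @rdname cai
#' @param counts_matrix Genes x 64 codon count matrix.
#' @return `cai_per_gene()`: named numeric vector, one CAI per gene.
#' @export
cai_per_gene <- function(counts_matrix, weights, code = genetic_code()) {
  x <- counts_matrix[, names(weights), drop = FALSE]
  L <- rowSums(x)
  out <- exp(as.numeric(x %*% log(weights)) / L)
  out[L == 0] <- NA_real_
  stats::setNames(out, rownames(counts_matrix))
}

#' Effective number of codons (ENC)
#'
#' Wright's estimator of how far codon usage departs from uniform synonymous
#' usage. For each family with n >= 2 codons observed, the homozygosity is
#' F = (n * sum(p^2) - 1) / (n - 1); F is averaged within each degeneracy
#' class and ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6. ENC is 20 when one codon
#' is used per amino acid and 61 under fully uniform usage; the returned
#' value is clamped to \[20, 61\].
#'
#' Missing-class handling: if the single threefold family (Ile) is
#' uninformative, its mean homozygosity is imputed as (F2 + F4)/2; any other
#' uninformative class is dropped and the remaining family terms rescaled by
#' the ratio of total to represented family counts. If no family has n >= 2
#' the estimator is undefined and `NA` is returned.
#'
#' @inheritParams composition
#' @return ENC in \[20, 61\], or `NA_real_` when undefined.
#' @export
enc <- function(counts, code = genetic_code()) {
  fam_F <- numeric(0)
  fam_k <- integer(0)
  for (fam in code$synonymous_families) {
    x <- as.numeric(counts[fam])
    n <- sum(x)
    if (n < 2) next
    p <- x / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    fam_F <- c(fam_F, f)
    fam_k <- c(fam_k, length(fam))
  }
  if (length(fam_F) == 0L) return(NA_real_)
  class_sizes <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)
  fbar <- vapply(c(2L, 3L, 6L, 4L), function(k) {
    mean(fam_F[fam_k == k])
  }, numeric(1))
  names(fbar) <- c("2", "3", "6", "4")
  fbar <- fbar[c("2", "3", "4", "6")]
  fbar[!is.finite(fbar) | fbar <= 1e-9] <- NA_real_
  if (is.na(fbar["3"]) && !is.na(fbar["2"]) && !is.na(fbar["4"])) {
    fbar["3"] <- (fbar["2"] + fbar["4"]) / 2
  }
  avail <- !is.na(fbar)
  if (!any(avail)) return(NA_real_)
  terms <- class_sizes[avail] / fbar[avail]
  scale <- sum(class_sizes) / sum(class_sizes[avail])
  out <- 2 + sum(terms) * scale
  min(61, max(20, out))
}

#' Codon bias index (CBI)
#'
#' Measures usage of a designated optimal-codon set relative to random
#' usage: CBI = (N_opt - N_ran) / (N_tot - N_ran), where N_tot is the total
#' count over families that contain an optimal codon, N_opt the count of
#' optimal codons, and N_ran the count expected under uniform usage
#' (sum of n_family / family size). CBI is 1 when only optimal codons are
#' used, 0 under uniform usage and negative when optimal codons are avoided.
#'
#' @param counts Named 64-codon count vector.
#' @param optimal Character vector of optimal codons, at most one per
#'   synonymous family.
#' @param code A [genetic_code()].
#' @return CBI in \[-1, 1\], or `NA_real_` when degenerate (N_tot = N_ran).
#' @export
cbi <- function(counts, optimal, code = genetic_code()) {
  parts <- .optimal_family_counts(counts, optimal, code)
  denom <- parts$n_tot - parts$n_ran
  if (abs(denom) < .Machine$double.eps * 64) return(NA_real_)
  (parts$n_opt - parts$n_ran) / denom
}

#' Frequency of optimal codons (FOP)
#'
#' Fraction of synonymous codons (in families that contain an optimal codon)
#' that are the optimal codon.
#'
#' @inheritParams cbi
#' @return FOP in \[0, 1\], or `NA_real_` when no covered codons are present.
#' @export
fop <- function(counts, optimal, code = genetic_code()) {
  parts <- .optimal_family_counts(counts, optimal, code)
  if (parts$n_tot == 0) return(NA_real_)
  parts$n_opt / parts$n_tot
}

.optimal_family_counts <- function(counts, optimal, code) {
  optimal <- intersect(optimal, code$synonymous_codons)
  n_tot <- 0
  n_opt <- 0
  n_ran <- 0
  for (fam in code$synonymous_families) {
    opt_in <- intersect(optimal, fam)
    if (length(opt_in) == 0L) next
    if (length(opt_in) > 1L) {
      stop("optimal set contains more than one codon for a synonymous ",
           "family: ", paste(opt_in, collapse = ", "))
    }
    n <- sum(counts[fam])
    n_tot <- n_tot + n
    n_opt <- n_opt + sum(counts[opt_in])
    n_ran <- n_ran + n / length(fam)
  }
  list(n_tot = n_tot, n_opt = n_opt, n_ran = n_ran)
}

#' Mean hydropathy (GRAVY) of the encoded protein
#'
#' Count-weighted mean Kyte-Doolittle hydropathy over the residues encoded
#' by the sense codons. Positive values indicate hydrophobic proteins,
#' negative values hydrophilic ones.
#'
#' @inheritParams composition
#' @return Mean hydropathy (the Kyte-Doolittle scale spans -4.5 to 4.5).
#' @export
gravy <- function(counts, code = genetic_code()) {
  x <- as.numeric(counts[code$sense_codons])
  n <- sum(x)
  if (n == 0) stop("gene has zero sense codons")
  h <- .kyte_doolittle[code$codon_aa[code$sense_codons]]
  sum(x * h) / n
}

#' Aromaticity (AROMO) of the encoded protein
#'
#' Fraction of encoded residues that are aromatic (Phe, Tyr, Trp).
#'
#' @inheritParams composition
#' @return Fraction in \[0, 1\].
#' @export
aromo <- function(counts, code = genetic_code()) {
  x <- as.numeric(counts[code$sense_codons])
  n <- sum(x)
  if (n == 0) stop("gene has zero sense codons")
  sum(x[code$codon_aa[code$sense_codons] %in% .aromatic_aa]) / n
}

#' Per-gene index table
#'
#' Joins all composition and CUB indices into one row per gene: gene length
#' in sense codons, GC1/GC2/GC3/GC12/GC3s/GC, third-position base counts,
#' ENC, GRAVY, AROMO, and - when the corresponding inputs are supplied -
#' CAI, CBI and FOP. Genes flagged short (see [qc_policy()]) keep their ENC
#' value but carry the flag.
#'
#' @param counts Genes x 64 codon count matrix.
#' @param code A [genetic_code()].
#' @param weights Optional CAI weights ([build_reference_weights()]).
#' @param optimal Optional optimal-codon set for CBI/FOP.
#' @param genome Optional genome label stored in a `genome` column.
#' @param short_flag_codons Genes with fewer sense codons are flagged.
#'
#' @return Data frame, one row per gene.
#' @export
gene_indices <- function(counts, code = genetic_code(), weights = NULL,
                         optimal = NULL, genome = NA_character_,
                         short_flag_codons = 100L) {
  comp <- apply(counts, 1L, composition, code = code)
  tab <- data.frame(
    id = rownames(counts),
    genome = genome,
    length_codons = vapply(comp, `[[`, integer(1), "n_sense"),
    gc1 = vapply(comp, `[[`, numeric(1), "gc1"),
    gc2 = vapply(comp, `[[`, numeric(1), "gc2"),
    gc3 = vapply(comp, `[[`, numeric(1), "gc3"),
    gc12 = vapply(comp, `[[`, numeric(1), "gc12"),
    gc3s = vapply(comp, `[[`, numeric(1), "gc3s"),
    gc = vapply(comp, `[[`, numeric(1), "gc"),
    a3 = vapply(comp, `[[`, integer(1), "a3"),
    u3 = vapply(comp, `[[`, integer(1), "u3"),
    g3 = vapply(comp, `[[`, integer(1), "g3"),
    c3 = vapply(comp, `[[`, integer(1), "c3"),
    enc = apply(counts, 1L, enc, code = code),
    gravy = apply(counts, 1L, gravy, code = code),
    aromo = apply(counts, 1L, aromo, code = code),
    stringsAsFactors = FALSE
  )
  tab$short_gene <- tab$length_codons < short_flag_codons
  if (!is.null(weights)) {
    tab$cai <- cai_per_gene(counts, weights, code)
  }
  if (!is.null(optimal)) {
    tab$cbi <- apply(counts, 1L, cbi, optimal = optimal, code = code)
    tab$fop <- apply(counts, 1L, fop, optimal = optimal, code = code)
  }
  rownames(tab) <- NULL
  tab
}
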