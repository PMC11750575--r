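# Correspondence analysis of per-gene RSCU profiles in 59-codon space.

#' Correspondence analysis of an RSCU (or count) matrix
#'
#' Classical correspondence analysis of a non-negative genes x codons
#' matrix, conventionally the per-gene RSCU matrix over the 59 synonymous
#' codons: the matrix is normalised to proportions P with row masses r and
#' column masses c, the standardised residual matrix
#' S = Dr^(-1/2) (P - r c') Dc^(-1/2) is decomposed by SVD, and genes and
#' codons are placed in principal coordinates. The inertia contribution of
#' axis k is its squared singular value as a percentage of the total.
#'
#' Rows with zero sums are removed (and reported); columns with zero sums
#' are removed likewise. If the matrix has no variation (all rows
#' proportional), a degenerate result with `no_variation = TRUE` is
#' returned. Since CA axes are defined only up to sign, an optional
#' `orient_by` vector (typically per-gene GC3s) fixes each axis's sign so
#' its correlation with that vector is non-negative, making outputs
#' reproducible across SVD implementations.
#'
#' @param x Non-negative matrix, genes in rows (rownames = gene ids),
#'   codons in columns; typically [rscu_matrix()] output.
#' @param n_axes Number of axes to keep in the coordinate matrices.
#' @param orient_by Optional numeric vector (length = number of retained
#'   genes) used to orient axis signs.
#'
#' @return Object of class `"coa"`: list with `gene_coords` and
#'   `codon_coords` (principal coordinates, up to `n_axes` columns),
#'   `contributions` (percent inertia per axis, all axes),
#'   `singular_values`, `total_inertia`, `n_axes`, `row_mass`, `col_mass`,
#'   `dropped_rows`, `dropped_cols`, `no_variation`.
#' @export
correspondence_analysis <- function(x, n_axes = 4L, orient_by = NULL) {
  stopifnot(is.matrix(x))
  if (any(x < 0)) stop("CA input must be non-negative")
  if (nrow(x) < 5L) stop("CA needs at least 5 genes")
  zero_rows <- rowSums(x) == 0
  zero_cols <- colSums(x) == 0
  dropped_rows <- rownames(x)[zero_rows]
  dropped_cols <- colnames(x)[zero_cols]
  x <- x[!zero_rows, !zero_cols, drop = FALSE]
  if (!is.null(orient_by)) orient_by <- orient_by[!zero_rows]
  N <- sum(x)
  P <- x / N
  r <- rowSums(P)
  cc <- colSums(P)
  S <- sweep(sweep(P - outer(r, cc), 1L, sqrt(r), "/"), 2L, sqrt(cc), "/")
  sv <- svd(S)
  inertia <- sv$d^2
  total <- sum(inertia)
  if (total < 1e-12) {
    return(structure(
      list(no_variation = TRUE, total_inertia = total,
           message = "no variation among rows; coordinates not computed",
           dropped_rows = dropped_rows, dropped_cols = dropped_cols),
      class = "coa"))
  }
  pos <- sv$d > sv$d[1L] * 1e-10
  if (sum(pos) < 2L) stop("degenerate CA input: rank < 2")
  d <- sv$d[pos]
  u <- sv$u[, pos, drop = FALSE]
  v <- sv$v[, pos, drop = FALSE]
  keep <- seq_len(min(n_axes, length(d)))
  F <- sweep(u, 1L, sqrt(r), "/") %*% diag(d, length(d))
  G <- sweep(v, 1L, sqrt(cc), "/") %*% diag(d, length(d))
  if (!is.null(orient_by) && stats::var(orient_by) > 0) {
    for (k in keep) {
      if (stats::var(F[, k]) > 0 &&
          stats::cor(F[, k], orient_by) < 0) {
        F[, k] <- -F[, k]
        G[, k] <- -G[, k]
      }
    }
  }
  ax <- paste0("axis", seq_along(d))
  dimnames(F) <- list(rownames(x), ax)
  dimnames(G) <- list(colnames(x), ax)
  structure(
    list(
      no_variation = FALSE,
      gene_coords = F[, keep, drop = FALSE],
      codon_coords = G[, keep, drop = FALSE],
      contributions = inertia / total * 100,
      singular_values = d,
      total_inertia = total,
      n_axes = length(keep),
      row_mass = r,
      col_mass = cc,
      dropped_rows = dropped_rows,
      dropped_cols = dropped_cols
    ),
    class = "coa"
  )
}

#' @export
print.coa <- function(x, ...) {
  if (isTRUE(x$no_variation)) {
    cat("Correspondence analysis:", x$message, "\n")
    return(invisible(x))
  }
  cat("Correspondence analysis:", nrow(x$gene_coords), "genes x",
      nrow(x$codon_coords), "codons\n")
  k <- min(4L, length(x$contributions))
  cat("Axis inertia contributions (%):",
      paste(sprintf("%.2f", x$contributions[seq_len(k)]), collapse = ", "),
      "...\n")
  invisible(x)
}

#' Correlation of CA axis 1 with codon-usage indices
#'
#' Pearson correlation (with two-sided p-values and 0.05 / 0.01 flags) of
#' the gene coordinates on CA axis 1 against selected indices of the
#' per-gene table. Gene ids must match between the CA result and the table.
#'
#' @param coa A [correspondence_analysis()] result.
#' @param table Per-gene index table with an `id` column.
#' @param traits Index columns to test.
#' @param axis Axis number (default 1).
#' @return Data frame: `trait`, `r`, `p_value`, `sig05`, `sig01`, `n`.
#' @export
axis_trait_correlations <- function(coa, table,
                                    traits = c("gc", "gc3s", "enc", "cai",
                                               "cbi", "fop"),
                                    axis = 1L) {
  if (isTRUE(coa$no_variation)) stop("CA result has no variation")
  ids <- rownames(coa$gene_coords)
  missing <- setdiff(ids, table$id)
  if (length(missing) > 0L) {
    stop("gene ids in CA result missing from index table: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ..." else "")
  }
  tab <- table[match(ids, table$id), , drop = FALSE]
  traits <- intersect(traits, names(tab))
  coord <- coa$gene_coords[, axis]
  rows <- lapply(traits, function(tr) {
    v <- tab[[tr]]
    ok <- is.finite(v) & is.finite(coord)
    if (sum(ok) < 3L || stats::var(v[ok]) == 0) {
      return(data.frame(trait = tr, r = NA_real_, p_value = NA_real_,
                        sig05 = NA, sig01 = NA, n = sum(ok)))
    }
    ct <- suppressWarnings(stats::cor.test(coord[ok], v[ok]))
    data.frame(trait = tr, r = unname(ct$estimate), p_value = ct$p.value,
               sig05 = ct$p.value < 0.05, sig01 = ct$p.value < 0.01,
               n = sum(ok))
  })
  do.call(rbind, rows)
}
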