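# Mutation-vs-selection diagnostics: neutrality regression, Wright's
# expected ENC curve, PR2-bias coordinates, pairwise index correlations.

#' Neutrality regression of GC12 on GC3
#'
#' Ordinary least squares of per-gene GC12 (mean G+C at codon positions 1
#' and 2) on GC3 across the genes of one genome, with the Pearson
#' correlation test. A slope near 1 with a significant correlation is read
#' as mutational pressure dominating codon usage; a slope near 0 as
#' selection dominating. The function reports the fit; the interpretation is
#' left to the analyst.
#'
#' @param table Per-gene index table ([gene_indices()]) with columns `gc12`
#'   and `gc3`.
#' @return Object of class `"neutrality_fit"`: list with `slope`,
#'   `intercept`, `r_squared`, `r`, `p_value`, `n`.
#' @export
neutrality_fit <- function(table) {
  stopifnot(all(c("gc12", "gc3") %in% names(table)))
  ok <- stats::complete.cases(table[, c("gc12", "gc3")])
  gc12 <- table$gc12[ok]
  gc3 <- table$gc3[ok]
  n <- length(gc3)
  if (n < 3L) stop("neutrality regression needs at least 3 genes")
  if (stats::var(gc3) == 0) {
    stop("GC3 is constant across genes; regression slope is undefined")
  }
  fit <- stats::lm(gc12 ~ gc3)
  if (stats::var(gc12) == 0) {
    # constant response: slope 0 exactly, no explainable variance
    r <- 0; r2 <- 0; p <- 1
  } else {
    ct <- stats::cor.test(gc3, gc12)
    r <- unname(ct$estimate)
    r2 <- summary(fit)$r.squared
    p <- ct$p.value
  }
  structure(
    list(
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      r_squared = r2,
      r = r,
      p_value = p,
      n = n
    ),
    class = "neutrality_fit"
  )
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf(
    "Neutrality fit (GC12 ~ GC3, n = %d): slope %.4f, R^2 %.4f, p %.3g\n",
    x$n, x$slope, x$r_squared, x$p_value))
  invisible(x)
}

#' Expected ENC under mutation-only codon usage
#'
#' Wright's expected curve on the ENC-GC3s plane: for silent-site G+C
#' content s, ENC_exp = 2 + s + 29 / (s^2 + (1 - s)^2). Genes lying near
#' this curve are compatible with codon usage shaped by mutational GC bias
#' alone; genes falling well below it suggest additional forces such as
#' translational selection.
#'
#' @param gc3s GC3s fraction(s) in \[0, 1\].
#' @return Expected ENC (vectorised).
#' @examples
#' enc_expected(0.5)  # 60.5, the curve's maximum
#' @export
enc_expected <- function(gc3s) {
  if (any(!is.finite(gc3s)) || any(gc3s < 0 | gc3s > 1)) {
    stop("gc3s must lie in [0, 1]")
  }
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' ENC ratio: relative deviation from the expected curve
#'
#' (ENC_exp - ENC_obs) / ENC_exp, where ENC_exp = [enc_expected()] at the
#' gene's GC3s. Positive values mean the observed ENC falls below the
#' mutation-only expectation.
#'
#' @param enc_obs Observed ENC value(s), in \[20, 61\].
#' @param gc3s GC3s fraction(s) in \[0, 1\].
#' @return ENC ratio (vectorised).
#' @export
enc_ratio <- function(enc_obs, gc3s) {
  e <- enc_expected(gc3s)
  (e - enc_obs) / e
}

#' Per-gene ENC-GC3s curve points
#'
#' @param table Per-gene index table with columns `gc3s` and `enc`.
#' @return Data frame: `id`, `gc3s`, `enc_obs`, `enc_exp`, `enc_ratio`.
#' @export
enc_curve_points <- function(table) {
  stopifnot(all(c("gc3s", "enc") %in% names(table)))
  ok <- is.finite(table$gc3s) & is.finite(table$enc)
  data.frame(
    id = if ("id" %in% names(table)) table$id[ok] else which(ok),
    gc3s = table$gc3s[ok],
    enc_obs = table$enc[ok],
    enc_exp = enc_expected(table$gc3s[ok]),
    enc_ratio = enc_ratio(table$enc[ok], table$gc3s[ok]),
    stringsAsFactors = FALSE
  )
}

#' Parity-rule-2 bias coordinates
#'
#' Per-gene PR2 coordinates x = G3/(G3+C3) and y = A3/(A3+U3) from
#' third-position base counts over sense codons. Under strand-symmetric
#' mutation with no selection both ratios are 0.5; the quadrant occupancy
#' summary shows how genes deviate. Genes with a zero denominator are
#' flagged and excluded from the summary.
#'
#' @param table Per-gene index table with columns `a3`, `u3`, `g3`, `c3`.
#' @return List with `points` (data frame: `id`, `x`, `y`, `quadrant`,
#'   `flagged`) and `quadrants` (named fractions over unflagged genes;
#'   quadrant labels combine `G3 > 0.5`/`G3 < 0.5` with `A3 > 0.5`/
#'   `A3 < 0.5`, boundaries assigned to the lower side).
#' @export
pr2_points <- function(table) {
  stopifnot(all(c("a3", "u3", "g3", "c3") %in% names(table)))
  gx <- table$g3 + table$c3
  ay <- table$a3 + table$u3
  flagged <- gx == 0 | ay == 0
  x <- ifelse(gx > 0, table$g3 / gx, NA_real_)
  y <- ifelse(ay > 0, table$a3 / ay, NA_real_)
  quadrant <- ifelse(flagged, NA_character_,
    paste0(ifelse(x > 0.5, "G3>0.5", "G3<=0.5"), ",",
           ifelse(y > 0.5, "A3>0.5", "A3<=0.5")))
  points <- data.frame(
    id = if ("id" %in% names(table)) table$id else seq_len(nrow(table)),
    x = x, y = y, quadrant = quadrant, flagged = flagged,
    stringsAsFactors = FALSE
  )
  lv <- c("G3<=0.5,A3<=0.5", "G3<=0.5,A3>0.5",
          "G3>0.5,A3<=0.5", "G3>0.5,A3>0.5")
  occ <- table(factor(quadrant[!flagged], levels = lv))
  quadrants <- if (sum(occ) > 0) as.numeric(occ) / sum(occ) else
    rep(NA_real_, 4L)
  names(quadrants) <- lv
  list(points = points, quadrants = quadrants)
}

#' Pairwise correlations among composition and CUB indices
#'
#' Pearson correlation of every index pair with two-sided p-values, flagged
#' at the 0.05 and 0.01 levels, plus Benjamini-Hochberg adjusted p-values.
#' Columns with zero variance (aromaticity can be near-constant) are kept
#' but their correlations are reported as missing.
#'
#' @param table Per-gene index table.
#' @param vars Index columns to correlate (defaults to those present among
#'   the standard set).
#' @return Object of class `"index_correlations"`: list with matrices `r`,
#'   `p`, `p_bh`, `sig05`, `sig01` and the variable names.
#' @export
index_correlations <- function(table,
                               vars = c("cai", "cbi", "fop", "gravy",
                                        "aromo", "enc", "gc1", "gc2", "gc3",
                                        "gc3s", "gc")) {
  vars <- intersect(vars, names(table))
  if (nrow(table) < 3L) stop("correlation analysis needs at least 3 genes")
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1
  diag(p) <- 0
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      xi <- table[[vars[i]]]
      xj <- table[[vars[j]]]
      ok <- is.finite(xi) & is.finite(xj)
      if (sum(ok) < 3L || stats::var(xi[ok]) == 0 ||
          stats::var(xj[ok]) == 0) next
      ct <- suppressWarnings(stats::cor.test(xi[ok], xj[ok]))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  p_bh <- p
  up <- upper.tri(p)
  p_bh[up] <- stats::p.adjust(p[up], method = "BH")
  p_bh[lower.tri(p_bh)] <- t(p_bh)[lower.tri(p_bh)]
  structure(
    list(vars = vars, r = r, p = p, p_bh = p_bh,
         sig05 = p < 0.05, sig01 = p < 0.01),
    class = "index_correlations"
  )
}

#' @export
print.index_correlations <- function(x, ...) {
  cat("Pairwise Pearson correlations among", length(x$vars), "indices\n")
  print(round(x$r, 3))
  invisible(x)
}
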