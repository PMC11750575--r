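# Independent brute-force oracles and small fixture builders. These are
# deliberately written as plain loops over the definitions, separate from
# the package's implementations.

CODE <- genetic_code()

# Direct RSCU: x_j / ((1/n) * sum of family counts).
oracle_rscu <- function(counts) {
  out <- numeric(0)
  for (aa in names(CODE$synonymous_families)) {
    fam <- CODE$synonymous_families[[aa]]
    tot <- sum(counts[fam])
    for (cod in fam) {
      out[cod] <- if (tot == 0) 0 else
        counts[cod] / ((1 / length(fam)) * tot)
    }
  }
  out
}

# Direct Wright ENC, valid when every degeneracy class is informative.
oracle_enc <- function(counts) {
  fbar <- list(`2` = c(), `3` = c(), `4` = c(), `6` = c())
  for (aa in names(CODE$synonymous_families)) {
    fam <- CODE$synonymous_families[[aa]]
    n <- sum(counts[fam])
    if (n < 2) next
    p <- counts[fam] / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    k <- as.character(length(fam))
    fbar[[k]] <- c(fbar[[k]], f)
  }
  f2 <- mean(fbar[["2"]]); f3 <- mean(fbar[["3"]])
  f4 <- mean(fbar[["4"]]); f6 <- mean(fbar[["6"]])
  val <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  min(61, max(20, val))
}

# Closed-form OLS of y on x.
oracle_ols <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  list(slope = slope, intercept = intercept, r = r, r_squared = r^2)
}

# Direct double-loop adjusted residuals of a contingency table.
oracle_adjusted_residuals <- function(m) {
  N <- sum(m)
  r <- rowSums(m)
  cc <- colSums(m)
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (r[i] == 0 || cc[j] == 0) next
      e <- r[i] * cc[j] / N
      out[i, j] <- (m[i, j] - e) /
        sqrt(e * (1 - r[i] / N) * (1 - cc[j] / N))
    }
  }
  out
}

# Random 64-codon count table with every synonymous family informative.
random_counts <- function(seed, lambda = 8) {
  set.seed(seed)
  counts <- setNames(rpois(64, lambda), CODE$codons)
  for (fam in CODE$synonymous_families) {
    if (sum(counts[fam]) < 2) counts[fam[1]] <- counts[fam[1]] + 2L
  }
  counts[CODE$stop_codons] <- 0L
  counts
}

# Build a sequence using each sense codon `counts` times (given order).
seq_from_codons <- function(codons) paste(codons, collapse = "")

make_cds <- function(seqs, ids = sprintf("g%03d", seq_along(seqs)),
                     genome = "test") {
  data.frame(id = ids, header = ids, seq = seqs, genome = genome,
             stringsAsFactors = FALSE)
}

# A gene body using exactly one codon per amino acid, repeated.
one_codon_per_aa_counts <- function(n_each = 5L) {
  counts <- setNames(integer(64), CODE$codons)
  for (fam in CODE$families) counts[fam[1]] <- n_each
  counts
}

uniform_counts <- function(n_each = 12L) {
  counts <- setNames(integer(64), CODE$codons)
  counts[CODE$sense_codons] <- n_each
  counts
}
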