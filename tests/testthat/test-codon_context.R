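test_that("pair counting enumerates adjacent pairs including stops", {
  m <- count_codon_pairs(make_cds("ATGGCTTAA"))
  expect_equal(m["ATG", "GCT"], 1L)
  expect_equal(m["GCT", "TAA"], 1L)
  expect_equal(sum(m), 2L)
  # self-pairs count
  m2 <- count_codon_pairs(make_cds("ATGCTGCTGTAA"))
  expect_equal(m2["CTG", "CTG"], 1L)
  # genes without a terminal stop are flagged, pairs still counted
  m3 <- count_codon_pairs(make_cds("ATGGCTGCC"))
  expect_equal(attr(m3, "no_stop"), "g001")
  expect_equal(sum(m3), 2L)
})

test_that("pair counts are additive and conserve gene pair totals", {
  cds1 <- make_cds(c("ATGGCTTAA", "ATGCTGCTGTAA"))
  cds2 <- make_cds("ATGGCCGCCTAA", ids = "g009")
  m1 <- count_codon_pairs(cds1)
  m2 <- count_codon_pairs(cds2)
  m12 <- count_codon_pairs(rbind(cds1, cds2))
  expect_equal(m12, m1 + m2, ignore_attr = TRUE)
  lens <- nchar(rbind(cds1, cds2)$seq) / 3
  expect_equal(sum(m12), sum(lens - 1))
})

test_that("adjusted residuals are zero at independence and match oracle", {
  # exact product structure: counts = r_i * c_j
  m <- outer(c(10L, 20L, 5L, 1L), c(3L, 7L, 2L, 8L))
  dimnames(m) <- list(CODE$codons[1:4], CODE$codons[5:8])
  res <- suppressWarnings(context_residuals(m))
  expect_true(all(abs(res$residuals) < 1e-9))
  # oracle equivalence on a random table
  set.seed(12)
  m2 <- matrix(rpois(64 * 64, 2), 64, 64,
               dimnames = list(CODE$codons, CODE$codons))
  res2 <- context_residuals(m2)
  expect_equal(res2$residuals, oracle_adjusted_residuals(m2),
               tolerance = 1e-9)
  # residual sum identity: sum(observed - expected) = 0
  expect_equal(sum(m2 - res2$expected), 0, tolerance = 1e-6)
})

test_that("zero-marginal cells are undefined and calls match threshold", {
  set.seed(5)
  m <- matrix(rpois(64 * 64, 3), 64, 64,
              dimnames = list(CODE$codons, CODE$codons))
  m["TAA", ] <- 0L   # stop codons never in 5' position of a pair? -> row 0
  res <- context_residuals(m, threshold = 3)
  expect_true(all(is.na(res$residuals["TAA", ])))
  expect_true(all(is.na(res$calls["TAA", ])))
  ok <- !is.na(res$residuals)
  expect_true(all((res$calls[ok] == "preferred") ==
                  (res$residuals[ok] > 3)))
  expect_true(all((res$calls[ok] == "avoided") ==
                  (res$residuals[ok] < -3)))
})

test_that("a planted over-represented pair is the top preferred call", {
  set.seed(77)
  r <- runif(64); r <- r / sum(r)
  cc <- runif(64); cc <- cc / sum(cc)
  p <- outer(r, cc)
  dimnames(p) <- list(CODE$codons, CODE$codons)
  p["GAT", "CGC"] <- p["GAT", "CGC"] * 10
  p <- p / sum(p)
  counts <- matrix(as.integer(rmultinom(1, 2e5, as.numeric(p))), 64, 64,
                   dimnames = list(CODE$codons, CODE$codons))
  res <- context_residuals(counts)
  mx <- which(res$residuals == max(res$residuals, na.rm = TRUE),
              arr.ind = TRUE)
  expect_equal(rownames(res$residuals)[mx[1]], "GAT")
  expect_equal(colnames(res$residuals)[mx[2]], "CGC")
  expect_equal(res$calls["GAT", "CGC"], "preferred")
})

test_that("start/stop context report picks forced neighbours", {
  # every gene starts ATG GTG ... -> most-used 3' context of AUG is GUG
  seqs <- replicate(30, paste0(
    "ATGGTG",
    paste(sample(c("GCT", "GCC", "AAA", "CCC"), 20, TRUE), collapse = ""),
    "TAA"))
  cds <- make_cds(seqs)
  pairs <- count_codon_pairs(cds)
  res <- suppressWarnings(context_residuals(pairs))
  rep <- start_stop_context(pairs, res)
  expect_equal(rep$start$most_used_3prime, "GUG")
  # stops only UAA -> UAG/UGA rows not applicable
  expect_equal(rep$stop$applicable, c(TRUE, FALSE, FALSE))
  expect_true(is.na(rep$stop$most_used_5prime[2]))
  # planted GCC before every stop
  seqs2 <- replicate(30, paste0(
    "ATG", paste(sample(c("GCT", "AAA", "CTG"), 20, TRUE), collapse = ""),
    "GCCTAA"))
  pairs2 <- count_codon_pairs(make_cds(seqs2))
  res2 <- suppressWarnings(context_residuals(pairs2))
  rep2 <- start_stop_context(pairs2, res2)
  expect_equal(rep2$stop$most_used_5prime[1], "GCC")
  # top pairs are sorted by count
  expect_true(all(diff(rep2$top_pairs$count) <= 0))
})

test_that("distinct pair types counts nonzero cells", {
  m <- count_codon_pairs(make_cds(c("ATGGCTTAA", "ATGGCTTAA")))
  expect_equal(pair_types(m), 2L)
})

test_that("context clustering groups replicate genomes", {
  set.seed(30)
  base <- matrix(rnorm(4096), 64, 64,
                 dimnames = list(CODE$codons, CODE$codons))
  other <- matrix(rnorm(4096), 64, 64,
                  dimnames = list(CODE$codons, CODE$codons))
  hc <- cluster_contexts(list(a = base, b = base + 1e-8, c = other))
  # the two near-copies are siblings at (near) zero height
  merged <- hc$merge[1, ]
  expect_setequal(hc$labels[-merged], c("a", "b"))
  expect_lt(hc$height[1], 1e-6)
  expect_error(cluster_contexts(list(a = base, b = base)), "at least 3")
  # distance of a genome to itself is zero
  expect_equal(unname(1 - cor(as.numeric(base), as.numeric(base))), 0)
})
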