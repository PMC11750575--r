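test_that("composition matches hand-enumerated base fractions", {
  # Met, Trp, Ala-GCT: only GCT belongs to a synonymous family; third base T
  x <- count_codons("ATGTGGGCT")
  comp <- composition(x)
  expect_equal(comp$gc3s, 0)
  # codons GCG + GCA: positions 1 and 2 are G,C in both, third G then A
  y <- count_codons("GCGGCA")
  comp2 <- composition(y)
  expect_equal(comp2$gc1, 1)
  expect_equal(comp2$gc2, 1)
  expect_equal(comp2$gc3, 0.5)
  expect_equal(comp2$gc12, 1)
  expect_equal(comp2$a3 + comp2$u3 + comp2$g3 + comp2$c3, comp2$n_sense)
})

test_that("composition is invariant to codon order", {
  counts <- random_counts(7)
  set.seed(1)
  shuffled <- sample(rep(CODE$sense_codons, counts[CODE$sense_codons]))
  comp1 <- composition(counts)
  comp2 <- composition(count_codons(seq_from_codons(shuffled)))
  expect_equal(comp1, comp2)
})

test_that("RSCU matches hand computation and the family-sum invariant", {
  counts <- setNames(integer(64), CODE$codons)
  counts[c("GCT", "GCC", "GCA", "GCG")] <- c(2L, 1L, 1L, 0L)
  r <- rscu(counts)
  expect_equal(unname(r[c("GCT", "GCC", "GCA", "GCG")]), c(2, 1, 1, 0))
  # uniform usage in every family -> RSCU 1 everywhere
  expect_true(all(abs(rscu(uniform_counts()) - 1) < 1e-12))
  # single codon used in a 2-fold family -> 2 / 0
  counts2 <- setNames(integer(64), CODE$codons)
  counts2[c("TTT", "TTC")] <- c(5L, 0L)
  r2 <- rscu(counts2)
  expect_equal(unname(r2[c("TTT", "TTC")]), c(2, 0))
  # family sums equal family sizes on random tables, and the oracle agrees
  for (seed in 1:20) {
    counts <- random_counts(seed)
    r <- rscu(counts)
    expect_equal(r[names(oracle_rscu(counts))], oracle_rscu(counts),
                 tolerance = 1e-12, ignore_attr = TRUE)
    for (fam in CODE$synonymous_families) {
      if (sum(counts[fam]) > 0) {
        expect_equal(sum(r[fam]), length(fam), tolerance = 1e-9)
      }
    }
  }
})

test_that("RSCU agrees with seqinr on a random gene", {
  skip_if_not_installed("seqinr")
  counts <- random_counts(42)
  codons <- rep(CODE$sense_codons, counts[CODE$sense_codons])
  r_pkg <- rscu(counts)
  r_ref <- seqinr::uco(unlist(strsplit(tolower(
    seq_from_codons(codons)), "")), index = "rscu")
  names(r_ref) <- toupper(names(r_ref))
  shared <- names(r_pkg)
  expect_equal(unname(r_pkg[shared]), unname(r_ref[shared]),
               tolerance = 1e-9)
})

test_that("reference weights follow the max-1 / pseudo-weight contract", {
  counts <- matrix(0L, 2, 64, dimnames = list(c("a", "b"), CODE$codons))
  counts[, "GCT"] <- 10L  # reference uses only GCT for Ala
  counts[, "TTT"] <- c(5L, 5L)
  w <- build_reference_weights(counts, selector = "list",
                               ids = c("a", "b"))
  expect_equal(unname(w["GCT"]), 1)
  expect_equal(unname(w[c("GCC", "GCA", "GCG")]), rep(0.01, 3))
  # uniform reference -> all weights 1
  uni <- matrix(rep(uniform_counts(), 2), 2, 64, byrow = TRUE,
                dimnames = list(c("a", "b"), CODE$codons))
  w2 <- build_reference_weights(uni, selector = "list", ids = c("a", "b"))
  expect_true(all(w2 == 1))
  expect_error(
    build_reference_weights(counts, selector = "annotation",
                            headers = c("x", "y")),
    "empty reference")
})

test_that("CAI is the geometric mean of weights", {
  w <- setNames(rep(1, 59), CODE$synonymous_codons)
  counts <- uniform_counts()
  expect_equal(cai(counts, w), 1)
  # two codons with w = 1 and w = 0.25 -> sqrt(0.25) = 0.5
  w2 <- w
  w2["TTC"] <- 0.25
  counts2 <- setNames(integer(64), CODE$codons)
  counts2[c("TTT", "TTC")] <- 1L
  expect_equal(cai(counts2, w2), 0.5)
  # invariant to codon order / duplication
  counts3 <- counts2 * 3L
  expect_equal(cai(counts3, w2), 0.5)
  expect_error(cai(setNames(integer(64), CODE$codons), w), "no scorable")
})

test_that("ENC hits its theoretical extremes", {
  expect_equal(enc(one_codon_per_aa_counts()), 20)
  expect_equal(enc(uniform_counts()), 61)
  # no informative family -> undefined
  counts <- setNames(integer(64), CODE$codons)
  counts["TTT"] <- 1L
  expect_true(is.na(enc(counts)))
})

test_that("ENC equals the brute-force Wright oracle on random tables", {
  for (seed in 1:300) {
    counts <- random_counts(seed)
    expect_equal(enc(counts), oracle_enc(counts), tolerance = 1e-9)
  }
})

test_that("CBI and FOP follow their definitions", {
  opt <- default_optimal_set()
  all_opt <- setNames(integer(64), CODE$codons)
  all_opt[opt] <- 10L
  expect_equal(cbi(all_opt, opt), 1)
  expect_equal(fop(all_opt, opt), 1)
  # uniform usage -> CBI 0, FOP = sum(n/size)/sum(n)
  uni <- uniform_counts()
  expect_equal(cbi(uni, opt), 0, tolerance = 1e-12)
  # uniform usage in 4-fold families only, optimal in each -> FOP 0.25
  counts4 <- setNames(integer(64), CODE$codons)
  four_fams <- CODE$synonymous_families[
    lengths(CODE$synonymous_families) == 4]
  for (fam in four_fams) counts4[fam] <- 3L
  opt4 <- vapply(four_fams, `[`, character(1), 1)
  expect_equal(fop(counts4, opt4), 0.25)
  # avoiding optimal codons in 2-fold families only -> CBI = -1
  two_fams <- CODE$synonymous_families[
    lengths(CODE$synonymous_families) == 2]
  counts2 <- setNames(integer(64), CODE$codons)
  for (fam in two_fams) counts2[fam[2]] <- 4L
  opt2 <- vapply(two_fams, `[`, character(1), 1)
  expect_equal(cbi(counts2, opt2), -1)
  expect_equal(fop(counts2, opt2), 0)
  # more than one optimal codon in a family is rejected
  expect_error(cbi(uni, c("TTT", "TTC")), "more than one codon")
})

test_that("GRAVY and AROMO match the residue tables", {
  ala <- setNames(integer(64), CODE$codons); ala["GCT"] <- 7L
  expect_equal(gravy(ala), 1.8)
  arg <- setNames(integer(64), CODE$codons); arg["CGT"] <- 3L
  expect_equal(gravy(arg), -4.5)
  # gene encoding M, F, Y -> AROMO 2/3
  mfy <- setNames(integer(64), CODE$codons)
  mfy[c("ATG", "TTT", "TAT")] <- 1L
  expect_equal(aromo(mfy), 2 / 3)
  expect_equal(aromo(ala), 0)
  trp <- setNames(integer(64), CODE$codons); trp["TGG"] <- 5L
  expect_equal(aromo(trp), 1)
})

test_that("indices are scale-invariant under count duplication", {
  counts <- random_counts(9)
  opt <- default_optimal_set()
  w <- setNames(runif(59, 0.1, 1), CODE$synonymous_codons)
  doubled <- counts * 2L
  expect_equal(cai(counts, w), cai(doubled, w))
  expect_equal(cbi(counts, opt), cbi(doubled, opt))
  expect_equal(fop(counts, opt), fop(doubled, opt))
  expect_equal(gravy(counts), gravy(doubled))
  expect_equal(aromo(counts), aromo(doubled))
  expect_equal(composition(counts)[c("gc1", "gc2", "gc3", "gc3s")],
               composition(doubled)[c("gc1", "gc2", "gc3", "gc3s")])
})

test_that("gene_indices joins all columns with one row per gene", {
  g <- generate_genome(synthetic_spec(mode = "mutation", n_genes = 30,
                                      seed = 5, label = "gi"))
  counts <- codon_count_matrix(qc_filter(g$cds)$retained)
  w <- build_reference_weights(counts, selector = "iterative")
  tab <- gene_indices(counts, weights = w,
                      optimal = default_optimal_set(), genome = "gi")
  expect_equal(nrow(tab), nrow(counts))
  expect_true(all(c("gc1", "gc2", "gc3", "gc12", "gc3s", "gc", "enc",
                    "gravy", "aromo", "cai", "cbi", "fop") %in% names(tab)))
  expect_true(all(is.finite(tab$cai)))
  expect_true(all(tab$gc3s >= 0 & tab$gc3s <= 1))
})
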