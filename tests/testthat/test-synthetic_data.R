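test_that("spec validation rejects invalid parameters", {
  expect_error(synthetic_spec(selection = -1), "selection")
  expect_error(synthetic_spec(theta_fixed = 1.5), "theta_fixed")
  expect_error(synthetic_spec(theta_shape1 = 0), "invalid distribution")
  expect_error(synthetic_spec(optimal_set = c("GCC", "GCT")), "one codon")
  expect_s3_class(synthetic_spec(), "synthetic_spec")
})

test_that("generation is deterministic given spec and seed", {
  sp <- synthetic_spec(mode = "mixed", n_genes = 20, selection = 1,
                       seed = 99, label = "det")
  g1 <- generate_genome(sp)
  g2 <- generate_genome(sp)
  expect_identical(g1$cds$seq, g2$cds$seq)
  expect_identical(g1$truth, g2$truth)
  # and FASTA bytes are identical
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_synthetic_genome(g1, d1)["fasta"]
  f2 <- write_synthetic_genome(g2, d2)["fasta"]
  expect_identical(readLines(f1), readLines(f2))
})

test_that("truth table and FASTA ids are in bijection", {
  g <- generate_genome(synthetic_spec(n_genes = 25, seed = 3))
  expect_setequal(g$cds$id, g$truth$id)
  expect_equal(anyDuplicated(g$cds$id), 0L)
})

test_that("generated genes are well-formed coding sequences", {
  g <- generate_genome(synthetic_spec(n_genes = 40, seed = 8))
  qc <- qc_filter(g$cds, qc_policy(min_codons = 5L))
  expect_equal(qc$summary$n_retained, 40L)
})

test_that("presets load, validate, and define the study conditions", {
  ps <- preset_suite(seed = 2)
  expect_setequal(names(ps), c("null-uniform", "mutation-dominated",
                               "selection-dominated", "mixed"))
  expect_equal(ps[["null-uniform"]]$theta_fixed, 0.5)
  expect_equal(ps[["mutation-dominated"]]$selection, 0)
  expect_gt(ps[["selection-dominated"]]$selection, 0)
})

test_that("null-uniform genome has near-uniform synonymous usage", {
  g <- generate_genome(preset_suite(seed = 17)[["null-uniform"]])
  counts <- codon_count_matrix(qc_filter(g$cds)$retained)
  r <- rscu(aggregate_counts(counts))
  expect_true(all(abs(r - 1) < 0.05))
})

test_that("genome GC3s tracks the mutational bias parameter", {
  for (theta in c(0.4, 0.6)) {
    sp <- synthetic_spec(mode = "mutation", n_genes = 500,
                         theta_fixed = theta, seed = 50 + theta * 10,
                         label = "gc3s")
    g <- generate_genome(sp)
    counts <- codon_count_matrix(qc_filter(g$cds)$retained)
    comp <- composition(aggregate_counts(counts))
    expect_lt(abs(comp$gc3s - theta), 0.02)
  }
})

test_that("codon frequencies match the analytic sampling probabilities", {
  # ~1e5 codons from one mutation-mode parameter set
  sp <- synthetic_spec(mode = "mutation", n_genes = 350,
                       theta_fixed = 0.55, seed = 61, label = "gof")
  g <- generate_genome(sp)
  counts <- aggregate_counts(
    codon_count_matrix(qc_filter(g$cds)$retained))
  probs <- codon_sampling_probs("mutation", 0.55)
  obs <- counts[names(probs)]
  # remove the forced ATG start from every gene before the fit
  obs["ATG"] <- obs["ATG"] - sp$n_genes
  gof <- suppressWarnings(chisq.test(obs, p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("selection-mode probabilities concentrate on the planted set", {
  opt <- default_optimal_set()
  p <- codon_sampling_probs("selection", theta = 0.5, expression = 8,
                            selection = 2, optimal_set = opt)
  # within every covered family nearly all mass is on the optimal codon
  for (fam in CODE$synonymous_families) {
    o <- intersect(fam, opt)
    expect_gt(p[o] / sum(p[fam]), 0.99)
  }
  # and a strongly selected genome drives FOP towards 1, ENC to the floor
  sp <- synthetic_spec(mode = "selection", n_genes = 60, selection = 6,
                       expression_rate = 0.2, theta_fixed = 0.5,
                       seed = 71, label = "strong")
  g <- generate_genome(sp)
  counts <- codon_count_matrix(qc_filter(g$cds)$retained)
  agg <- aggregate_counts(counts)
  expect_gt(fop(agg, opt), 0.95)
  expect_lt(enc(agg), 30)
})

test_that("planted context pairs are enriched in generated genomes", {
  pairs <- context_regime_pairs("A", n_pairs = 30)
  sp <- synthetic_spec(mode = "mutation", n_genes = 120,
                       theta_fixed = 0.5, context_pairs = pairs,
                       context_strength = 1.5, seed = 81,
                       label = "ctx", length_meanlog = log(150))
  g <- generate_genome(sp)
  pm <- count_codon_pairs(qc_filter(g$cds, qc_policy(min_codons = 5))$retained)
  res <- context_residuals(pm)
  planted <- res$residuals[pairs]
  background <- mean(res$residuals, na.rm = TRUE)
  expect_gt(mean(planted, na.rm = TRUE), background + 2)
})
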