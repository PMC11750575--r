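# Truth-annotated synthetic CDS genomes under a mutation-selection codon
# model. The generator is the package's test substrate: every downstream
# stage can be checked against the generating parameters.

# Average amino-acid background frequencies of bacterial proteomes
# (Swiss-Prot composition, normalised); used by the selection-mode sampler.
.default_aa_freqs <- local({
  f <- c(A = 0.089, R = 0.055, N = 0.040, D = 0.055, C = 0.012,
         Q = 0.039, E = 0.063, G = 0.072, H = 0.022, I = 0.056,
         L = 0.100, K = 0.052, M = 0.024, F = 0.039, P = 0.047,
         S = 0.066, T = 0.054, W = 0.011, Y = 0.029, V = 0.069)
  f / sum(f)
})

#' Default planted optimal-codon set
#'
#' One codon per synonymous family (18 families under code 11): the first
#' C-ending codon of the family, or the first G-ending codon when the family
#' has no C-ending member. Every family with degeneracy >= 2 is covered.
#'
#' @param code A [genetic_code()].
#' @return Character vector of 18 codons.
#' @export
default_optimal_set <- function(code = genetic_code()) {
  vapply(code$synonymous_families, function(fam) {
    third <- substring(fam, 3L, 3L)
    if (any(third == "C")) fam[third == "C"][1L] else fam[third == "G"][1L]
  }, character(1), USE.NAMES = FALSE)
}

#' Specification of a synthetic genome
#'
#' Defines the generative model for one genome. Genes are independent; each
#' gene g has a mutational GC bias theta_g (silent-site G+C propensity) and
#' an expression level e_g, and codons are sampled by mode:
#' \describe{
#'   \item{mutation}{codon probability proportional to the product of its
#'     three base weights (G and C weigh theta_g/2, A and T (1-theta_g)/2),
#'     restricted to sense codons - amino-acid usage co-varies with
#'     theta_g, as under genome-wide mutational pressure.}
#'   \item{selection}{amino acids drawn from a fixed background; within each
#'     family the codon probability is proportional to
#'     exp(selection * e_g * \[codon in optimal set\]) times the
#'     third-base mutational weight at a genome-constant theta. Expression
#'     enters multiplicatively in the exponent, creating the CAI gradient
#'     the optimal-codon machinery needs.}
#'   \item{mixed}{selection-mode sampling with per-gene theta_g.}
#' }
#' Each gene starts with ATG, ends with one stop codon drawn from
#' `stop_weights`, and has a lognormal body length. An optional first-order
#' context term enriches a planted set of adjacent codon pairs: the next
#' codon's probability is multiplied by exp(`context_strength`) when the
#' (previous, next) pair is in `context_pairs`. With `context_strength = 0`
#' (default) codons are drawn independently.
#'
#' @param mode `"mutation"`, `"selection"` or `"mixed"`.
#' @param n_genes Number of genes.
#' @param length_meanlog,length_sdlog Lognormal parameters of the body
#'   length in codons (defaults centre near 300 codons).
#' @param theta_shape1,theta_shape2 Beta parameters of the per-gene GC bias
#'   theta_g.
#' @param theta_fixed If non-`NULL`, a constant theta used for every gene
#'   (required meaning in selection mode; defaults there to the Beta mean).
#' @param expression_rate Rate of the exponential expression distribution.
#' @param selection Selection strength s >= 0.
#' @param optimal_set Planted optimal codons, one per synonymous family.
#' @param aa_freqs Amino-acid background frequencies (selection/mixed).
#' @param stop_weights Named sampling weights for TAA/TAG/TGA.
#' @param context_pairs Optional 2-column character matrix (from, to) of
#'   planted codon pairs.
#' @param context_strength Log-scale enrichment of planted pairs.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @param label Genome label used in FASTA ids and outputs.
#' @return Object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(mode = c("mixed", "mutation", "selection"),
                           n_genes = 500L,
                           length_meanlog = log(300),
                           length_sdlog = 0.25,
                           theta_shape1 = 2,
                           theta_shape2 = 2,
                           theta_fixed = NULL,
                           expression_rate = 1,
                           selection = 0,
                           optimal_set = default_optimal_set(),
                           aa_freqs = .default_aa_freqs,
                           stop_weights = c(TAA = 0.6, TAG = 0.2,
                                            TGA = 0.2),
                           context_pairs = NULL,
                           context_strength = 0,
                           seed = 1L,
                           label = "synthetic") {
  mode <- match.arg(mode)
  if (selection < 0) stop("selection strength must be >= 0")
  if (!is.null(theta_fixed) &&
      (theta_fixed <= 0 || theta_fixed >= 1)) {
    stop("theta_fixed must lie in (0, 1)")
  }
  if (theta_shape1 <= 0 || theta_shape2 <= 0 || expression_rate <= 0 ||
      length_sdlog < 0 || n_genes < 1L) {
    stop("invalid distribution parameters")
  }
  if (abs(sum(aa_freqs) - 1) > 1e-6 || any(aa_freqs < 0)) {
    stop("aa_freqs must be a probability vector over the 20 amino acids")
  }
  if (any(stop_weights < 0) || sum(stop_weights) <= 0) {
    stop("invalid stop_weights")
  }
  code <- genetic_code()
  fam_of <- code$codon_aa[intersect(optimal_set, code$synonymous_codons)]
  if (length(fam_of) != length(optimal_set) || anyDuplicated(fam_of) ||
      length(optimal_set) != length(code$synonymous_families)) {
    stop("optimal_set must contain exactly one codon per synonymous family")
  }
  if (mode == "selection" && is.null(theta_fixed)) {
    theta_fixed <- theta_shape1 / (theta_shape1 + theta_shape2)
  }
  structure(
    list(mode = mode, n_genes = as.integer(n_genes),
         length_meanlog = length_meanlog, length_sdlog = length_sdlog,
         theta_shape1 = theta_shape1, theta_shape2 = theta_shape2,
         theta_fixed = theta_fixed, expression_rate = expression_rate,
         selection = selection, optimal_set = optimal_set,
         aa_freqs = aa_freqs, stop_weights = stop_weights,
         context_pairs = context_pairs,
         context_strength = context_strength,
         seed = as.integer(seed), label = label),
    class = "synthetic_spec"
  )
}

#' Analytic codon sampling probabilities of the synthetic model
#'
#' The per-codon probabilities the generator draws from, exposed so that
#' generated codon frequencies can be checked against their analytic values.
#'
#' @param mode Sampling mode (see [synthetic_spec()]).
#' @param theta Mutational GC bias for this gene.
#' @param expression Expression level e_g (selection/mixed modes).
#' @param selection Selection strength s.
#' @param optimal_set Planted optimal codons.
#' @param aa_freqs Amino-acid background frequencies.
#' @param code A [genetic_code()].
#' @return Named probability vector over the 61 sense codons.
#' @export
codon_sampling_probs <- function(mode, theta, expression = 0,
                                 selection = 0,
                                 optimal_set = default_optimal_set(),
                                 aa_freqs = .default_aa_freqs,
                                 code = genetic_code()) {
  base_w <- c(A = (1 - theta) / 2, C = theta / 2,
              G = theta / 2, T = (1 - theta) / 2)
  if (mode == "mutation") {
    b <- do.call(rbind, strsplit(code$sense_codons, ""))
    w <- base_w[b[, 1L]] * base_w[b[, 2L]] * base_w[b[, 3L]]
    p <- w / sum(w)
    names(p) <- code$sense_codons
    return(p)
  }
  p <- stats::setNames(numeric(length(code$sense_codons)),
                       code$sense_codons)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    w3 <- base_w[substring(fam, 3L, 3L)]
    boost <- exp(selection * expression * (fam %in% optimal_set))
    w <- w3 * boost
    p[fam] <- aa_freqs[aa] * w / sum(w)
  }
  p
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic genome
#'
#' Draws per-gene parameters and sequences according to a
#' [synthetic_spec()] and returns the coding sequences together with the
#' generating truth. Identical spec and seed give identical output.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `"synthetic_genome"`: `cds` (data frame: `id`,
#'   `header`, `seq`, `genome`), `truth` (data frame: `id`, `theta`,
#'   `expression`, `mode`), and `spec`. The planted optimal set and
#'   selection strength are carried in `spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  code <- genetic_code()
  .with_seed(spec$seed, {
    n <- spec$n_genes
    lens <- pmax(10L, as.integer(round(
      stats::rlnorm(n, spec$length_meanlog, spec$length_sdlog))))
    theta <- if (!is.null(spec$theta_fixed)) {
      rep(spec$theta_fixed, n)
    } else {
      stats::rbeta(n, spec$theta_shape1, spec$theta_shape2)
    }
    expr <- stats::rexp(n, spec$expression_rate)
    stops <- sample(names(spec$stop_weights), n, replace = TRUE,
                    prob = spec$stop_weights)
    boost <- NULL
    if (!is.null(spec$context_pairs) && spec$context_strength != 0) {
      boost <- matrix(1, length(code$sense_codons),
                      length(code$sense_codons),
                      dimnames = list(code$sense_codons,
                                      code$sense_codons))
      boost[spec$context_pairs] <- exp(spec$context_strength)
    }
    seqs <- character(n)
    for (g in seq_len(n)) {
      p <- codon_sampling_probs(spec$mode, theta[g], expr[g],
                                spec$selection, spec$optimal_set,
                                spec$aa_freqs, code)
      if (is.null(boost)) {
        body <- sample(code$sense_codons, lens[g], replace = TRUE,
                       prob = p)
      } else {
        body <- character(lens[g])
        body[1L] <- sample(code$sense_codons, 1L, prob = p)
        for (i in seq.int(2L, lens[g])) {
          q <- p * boost[body[i - 1L], ]
          body[i] <- sample(code$sense_codons, 1L, prob = q)
        }
      }
      seqs[g] <- paste0("ATG", paste(body, collapse = ""), stops[g])
    }
    ids <- sprintf("%s_g%04d", spec$label, seq_len(n))
    structure(
      list(
        cds = data.frame(id = ids, header = ids, seq = seqs,
                         genome = spec$label, stringsAsFactors = FALSE),
        truth = data.frame(id = ids, theta = theta, expression = expr,
                           mode = spec$mode, stringsAsFactors = FALSE),
        spec = spec
      ),
      class = "synthetic_genome"
    )
  })
}

#' Write a synthetic genome to disk
#'
#' Emits the CDS FASTA, the truth table as TSV, and the spec as JSON.
#'
#' @param genome A [generate_genome()] result.
#' @param dir Output directory (created if missing).
#' @param name Base file name (defaults to the genome label).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_genome <- function(genome, dir, name = NULL) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (is.null(name)) name <- genome$spec$label
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, paste0(name, ".fasta"))
  seqs <- Biostrings::DNAStringSet(genome$cds$seq)
  names(seqs) <- genome$cds$id
  Biostrings::writeXStringSet(seqs, fasta)
  truth <- file.path(dir, paste0(name, "_truth.tsv"))
  utils::write.table(genome$truth, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  spec_json <- file.path(dir, paste0(name, "_spec.json"))
  sp <- genome$spec
  sp$context_pairs <- if (is.null(sp$context_pairs)) NULL else
    apply(sp$context_pairs, 1L, paste, collapse = "-")
  jsonlite::write_json(unclass(sp), spec_json, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(fasta = fasta, truth = truth, spec = spec_json))
}

#' Named preset synthetic-genome specifications
#'
#' Four study conditions used throughout the tests:
#' \describe{
#'   \item{null-uniform}{theta fixed at 0.5, no selection - every family is
#'     used uniformly in expectation.}
#'   \item{mutation-dominated}{per-gene theta from Beta(2, 2), no
#'     selection - codon usage tracks mutational GC bias at all positions.}
#'   \item{selection-dominated}{constant theta 0.55, selection strength 1.5
#'     on the planted optimal set with exponential expression spread.}
#'   \item{mixed}{per-gene theta plus selection strength 1.}
#' }
#' All presets use 500 genes of about 300 codons.
#'
#' @param seed Base seed; each preset derives its own offset seed.
#' @param n_genes Number of genes per genome.
#' @return Named list of [synthetic_spec()] objects.
#' @export
preset_suite <- function(seed = 1L, n_genes = 500L) {
  list(
    "null-uniform" = synthetic_spec(
      mode = "mutation", n_genes = n_genes, theta_fixed = 0.5,
      selection = 0, seed = seed, label = "null_uniform"),
    "mutation-dominated" = synthetic_spec(
      mode = "mutation", n_genes = n_genes, theta_shape1 = 2,
      theta_shape2 = 2, selection = 0, seed = seed + 1L,
      label = "mutation_dom"),
    "selection-dominated" = synthetic_spec(
      mode = "selection", n_genes = n_genes, theta_fixed = 0.55,
      selection = 1.5, expression_rate = 1, seed = seed + 2L,
      label = "selection_dom"),
    "mixed" = synthetic_spec(
      mode = "mixed", n_genes = n_genes, theta_shape1 = 2,
      theta_shape2 = 2, selection = 1, seed = seed + 3L,
      label = "mixed")
  )
}

#' Planted codon-pair sets for context-regime simulations
#'
#' Two distinct deterministic sets of adjacent codon pairs used to plant
#' distinguishable codon-context regimes in synthetic genomes.
#'
#' @param regime `"A"` or `"B"`.
#' @param n_pairs Number of planted pairs.
#' @param code A [genetic_code()].
#' @return Two-column character matrix (from, to).
#' @export
context_regime_pairs <- function(regime = c("A", "B"), n_pairs = 40L,
                                 code = genetic_code()) {
  regime <- match.arg(regime)
  s <- code$sense_codons
  i <- seq_len(n_pairs)
  if (regime == "A") {
    cbind(from = s[(i - 1L) %% 61L + 1L],
          to = s[(i * 7L) %% 61L + 1L])
  } else {
    cbind(from = s[(i + 19L) %% 61L + 1L],
          to = s[(i * 11L + 3L) %% 61L + 1L])
  }
}
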