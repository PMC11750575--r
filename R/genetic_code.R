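#' Bacterial genetic code (translation table 11)
#'
#' Builds the genetic-code object used throughout the package: the codon to
#' amino-acid map of NCBI translation table 11, the partition of the 61 sense
#' codons into synonymous families, degeneracy classes, and the stop-codon
#' set. All indices in the package (RSCU, CAI, ENC, ...) are defined relative
#' to this object; Met (ATG) and Trp (TGG) form single-codon families and are
#' excluded from synonymous-usage statistics, leaving 59 synonymous sense
#' codons.
#'
#' @param table_id Genetic code table number; only 11 (bacterial/archaeal/
#'   plant plastid) is supported.
#'
#' @return An object of class `"genetic_code"`: a list with elements
#'   `table_id`, `codon_aa` (named character, 64 codons to one-letter amino
#'   acid, `"*"` for stops), `codons` (all 64), `sense_codons` (61),
#'   `stop_codons` (TAA/TAG/TGA), `synonymous_codons` (the 59 codons of
#'   families with degeneracy >= 2), `families` (amino acid -> codon vector),
#'   `synonymous_families` (families with >= 2 codons), and `degeneracy`
#'   (named integer per sense codon).
#'
#' @examples
#' code <- genetic_code()
#' length(code$sense_codons)      # 61
#' code$families[["I"]]           # the threefold Ile family
#' @export
genetic_code <- function(table_id = 11L) {
  if (!identical(as.integer(table_id), 11L)) {
    stop("only genetic code table 11 is supported")
  }
  map <- Biostrings::getGeneticCode("11")
  codons <- names(map)
  stops <- codons[map == "*"]
  sense <- codons[map != "*"]
  families <- split(sense, factor(map[sense], levels = unique(map[sense])))
  degeneracy <- stats::setNames(lengths(families)[map[sense]], sense)
  syn_families <- families[lengths(families) >= 2L]
  structure(
    list(
      table_id = 11L,
      codon_aa = map,
      codons = codons,
      sense_codons = sense,
      stop_codons = stops,
      synonymous_codons = unname(unlist(syn_families)),
      families = families,
      synonymous_families = syn_families,
      degeneracy = degeneracy
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code table", x$table_id, "-",
      length(x$sense_codons), "sense codons,",
      length(x$stop_codons), "stop codons\n")
  cat("Synonymous families (degeneracy >= 2):",
      length(x$synonymous_families), "covering",
      length(x$synonymous_codons), "codons\n")
  invisible(x)
}

# Kyte-Doolittle hydropathy scale, one value per amino acid.
.kyte_doolittle <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

.aromatic_aa <- c("F", "Y", "W")

#' Split a coding sequence into codons
#'
#' @param seq A single nucleotide string whose length is a multiple of 3.
#' @return Character vector of consecutive non-overlapping triplets.
#' @export
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n == 0L || n %% 3L != 0L) {
    stop("sequence length (", n, ") is not a positive multiple of 3")
  }
  substring(seq, seq.int(1L, n - 2L, by = 3L), seq.int(3L, n, by = 3L))
}

#' Convert codon labels between DNA and RNA alphabets
#'
#' Reports in the codon-context module use the RNA alphabet (UAA, UAG, UGA)
#' common in the codon-usage literature, while all internal computation uses
#' DNA codons.
#'
#' @param codons Character vector of codons.
#' @return The same codons with T replaced by U (`codon_to_rna`) or U by T
#'   (`codon_to_dna`).
#' @export
codon_to_rna <- function(codons) chartr("T", "U", codons)

#' @rdname codon_to_rna
#' @export
codon_to_dna <- function(codons) chartr("U", "T", codons)
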