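#' Read coding sequences from a (multi-)FASTA file
#'
#' Reads nucleotide CDS records, normalises them to an upper-case DNA
#' alphabet (U is mapped to T so RNA exports are accepted), and returns one
#' row per record. No filtering happens here: malformed sequences are kept
#' and rejected later by [qc_filter()], so that the QC report can account for
#' every input gene.
#'
#' @param path Path to a FASTA file (gzip-compressed accepted).
#' @param genome Genome label attached to every record; defaults to the file
#'   name without its FASTA extension.
#'
#' @return A data frame with columns `id` (first whitespace-delimited header
#'   token), `header` (full header), `seq` and `genome`.
#' @seealso [qc_filter()], [count_codons()]
#' @export
read_cds_fasta <- function(path, genome = NULL) {
  if (!file.exists(path)) {
    stop("cannot read FASTA file: ", path)
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    stop("no sequences found in FASTA file: ", path)
  }
  headers <- names(seqs)
  ids <- vapply(strsplit(headers, "[[:space:]]+"), `[[`, character(1), 1L)
  if (is.null(genome)) {
    genome <- sub("\\.(fa|fasta|fna|ffn)(\\.gz)?$", "", basename(path),
                  ignore.case = TRUE)
  }
  data.frame(
    id = ids,
    header = headers,
    seq = gsub("[[:space:]]", "",
               toupper(chartr("Uu", "Tt", as.character(seqs)))),
    genome = genome,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Quality-control policy for coding sequences
#'
#' The rule set applied by [qc_filter()]. A clean reading frame (length
#' divisible by 3) is always required; every other rule can be toggled.
#' Bacterial alternative start codons GTG and TTG are accepted by default.
#'
#' @param require_start Require the first codon to be in `start_codons`.
#' @param start_codons Accepted initiator codons.
#' @param require_stop Require the final codon to be a stop codon.
#' @param forbid_internal_stop Reject genes with a stop codon before the
#'   final position.
#' @param forbid_ambiguous Reject genes containing non-ACGT characters. With
#'   `ambiguous_action = "drop-codon"` the offending codons are removed
#'   (frame preserved) instead of discarding the gene.
#' @param ambiguous_action `"discard"` (default) or `"drop-codon"`.
#' @param min_codons Minimum gene length in codons, stop included.
#' @param flag_short_codons Genes with fewer sense codons than this are
#'   retained but flagged: ENC is unstable on short genes.
#'
#' @return A list of class `"qc_policy"`.
#' @export
qc_policy <- function(require_start = TRUE,
                      start_codons = c("ATG", "GTG", "TTG"),
                      require_stop = TRUE,
                      forbid_internal_stop = TRUE,
                      forbid_ambiguous = TRUE,
                      ambiguous_action = c("discard", "drop-codon"),
                      min_codons = 30L,
                      flag_short_codons = 100L) {
  structure(
    list(
      require_start = isTRUE(require_start),
      start_codons = toupper(start_codons),
      require_stop = isTRUE(require_stop),
      forbid_internal_stop = isTRUE(forbid_internal_stop),
      forbid_ambiguous = isTRUE(forbid_ambiguous),
      ambiguous_action = match.arg(ambiguous_action),
      min_codons = as.integer(min_codons),
      flag_short_codons = as.integer(flag_short_codons)
    ),
    class = "qc_policy"
  )
}

#' Filter coding sequences against a QC policy
#'
#' Applies the rules of a [qc_policy()] to each sequence and splits the input
#' into retained and discarded genes. Failures are reported, never raised:
#' the report has one row per input gene with all failure reasons, so
#' retained + discarded always equals the input count.
#'
#' @param cds Data frame from [read_cds_fasta()] (columns `id`, `seq`, and
#'   optionally `genome`).
#' @param policy A [qc_policy()].
#' @param code A [genetic_code()].
#'
#' @return A list with elements `retained` (data frame like `cds`, plus a
#'   logical `short_gene` flag), `report` (data frame: `id`, `pass`,
#'   `reasons`) and `summary` (list: `n_input`, `n_retained`, `n_discarded`).
#' @export
qc_filter <- function(cds, policy = qc_policy(), code = genetic_code()) {
  stopifnot(is.data.frame(cds), all(c("id", "seq") %in% names(cds)))
  n <- nrow(cds)
  reasons <- vector("list", n)
  seqs <- cds$seq
  for (i in seq_len(n)) {
    s <- seqs[i]
    why <- character(0)
    if (nchar(s) %% 3L != 0L || nchar(s) == 0L) {
      why <- c(why, "length not divisible by 3")
      reasons[[i]] <- why
      next
    }
    ambiguous <- grepl("[^ACGT]", s)
    if (ambiguous && policy$forbid_ambiguous) {
      if (policy$ambiguous_action == "discard") {
        why <- c(why, "ambiguous base")
      } else {
        cod <- split_codons(s)
        cod <- cod[!grepl("[^ACGT]", cod)]
        s <- paste(cod, collapse = "")
        seqs[i] <- s
        if (nchar(s) == 0L) why <- c(why, "ambiguous base")
      }
    }
    if (nchar(s) >= 3L && !grepl("[^ACGT]", s)) {
      cod <- split_codons(s)
      L <- length(cod)
      if (policy$require_start && !(cod[1L] %in% policy$start_codons)) {
        why <- c(why, "missing start")
      }
      has_stop <- cod[L] %in% code$stop_codons
      if (policy$require_stop && !has_stop) {
        why <- c(why, "missing terminal stop")
      }
      if (policy$forbid_internal_stop && L > 1L &&
          any(cod[-L] %in% code$stop_codons)) {
        why <- c(why, "internal stop")
      }
      if (L < policy$min_codons) {
        why <- c(why, "below minimum codon count")
      }
    }
    reasons[[i]] <- why
  }
  pass <- lengths(reasons) == 0L
  retained <- cds[pass, , drop = FALSE]
  retained$seq <- seqs[pass]
  if (nrow(retained) > 0L) {
    sense_len <- vapply(retained$seq, function(s) {
      cod <- split_codons(s)
      sum(cod %in% code$sense_codons)
    }, integer(1))
    retained$short_gene <- sense_len < policy$flag_short_codons
  } else {
    retained$short_gene <- logical(0)
  }
  rownames(retained) <- NULL
  report <- data.frame(
    id = cds$id,
    pass = pass,
    reasons = vapply(reasons, paste, character(1), collapse = "; "),
    stringsAsFactors = FALSE
  )
  list(
    retained = retained,
    report = report,
    summary = list(n_input = n, n_retained = sum(pass),
                   n_discarded = sum(!pass))
  )
}

#' Write a QC report as TSV and JSON
#'
#' @param qc Result of [qc_filter()].
#' @param tsv_path,json_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the report data frame.
#' @export
write_qc_report <- function(qc, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(qc$report, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(qc$summary, json_path, auto_unbox = TRUE)
  }
  invisible(qc$report)
}

#' Count codons of a coding sequence
#'
#' Counts consecutive non-overlapping triplets from position 1. The terminal
#' stop codon, if present, is only counted when `include_stop = TRUE`; all
#' downstream indices operate on sense codons, while the codon-pair context
#' analysis keeps the stop.
#'
#' @param seq A nucleotide string, length divisible by 3.
#' @param include_stop Keep the terminal stop codon in the counts?
#' @param code A [genetic_code()].
#'
#' @return Named integer vector of length 64 (all codons of the code, fixed
#'   order), with attribute `total`.
#' @examples
#' count_codons("ATGGCTGCTGCCTAA")[c("ATG", "GCT", "GCC")]
#' @export
count_codons <- function(seq, include_stop = FALSE, code = genetic_code()) {
  cod <- split_codons(seq)
  if (!include_stop && cod[length(cod)] %in% code$stop_codons) {
    cod <- cod[-length(cod)]
  }
  counts <- tabulate(factor(cod, levels = code$codons),
                     nbins = length(code$codons))
  names(counts) <- code$codons
  structure(counts, total = sum(counts))
}

#' Per-gene codon count matrix
#'
#' @param cds Data frame with columns `id` and `seq` (QC-passed sequences).
#' @inheritParams count_codons
#' @return Integer matrix, genes x 64 codons, rownames = gene ids.
#' @export
codon_count_matrix <- function(cds, include_stop = FALSE,
                               code = genetic_code()) {
  stopifnot(is.data.frame(cds), all(c("id", "seq") %in% names(cds)))
  m <- t(vapply(cds$seq, function(s) {
    as.integer(count_codons(s, include_stop = include_stop, code = code))
  }, integer(length(code$codons))))
  dimnames(m) <- list(cds$id, code$codons)
  m
}

#' Aggregate per-gene codon counts into a genome-level table
#'
#' @param counts Matrix from [codon_count_matrix()] or a named count vector.
#' @return Named integer vector of length 64 (additive over genes).
#' @export
aggregate_counts <- function(counts) {
  if (is.matrix(counts)) {
    out <- colSums(counts)
  } else {
    out <- counts
  }
  storage.mode(out) <- "integer"
  structure(out, total = sum(out))
}
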