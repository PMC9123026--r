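#' The standard genetic code (or an NCBI translation table)
#'
#' A named character vector mapping each of the 64 trinucleotides to an
#' amino-acid letter, with `"*"` for stop. The standard table has 61 sense
#' codons encoding 20 amino acids.
#'
#' @param table_id NCBI genetic-code table id (default "1", the standard
#'   code).
#' @return named character vector of length 64.
#' @export
standard_genetic_code <- function(table_id = "1") {
  Biostrings::getGeneticCode(table_id)
}

#' Translate a coding sequence
#'
#' Standard-code translation of an A/C/G/T nucleotide string. A terminal stop
#' codon is trimmed (not translated); an internal stop is an error, since a
#' coding sequence with a premature stop cannot be aligned to a chain.
#'
#' @param nt_sequence nucleotide string, length divisible by 3.
#' @param code genetic code, see [standard_genetic_code()].
#' @return amino-acid string.
#' @examples
#' translate_cds("ATGAAA")  # "MK"
#' translate_cds("ATGTAA")  # "M"
#' @export
translate_cds <- function(nt_sequence, code = standard_genetic_code()) {
  nt_sequence <- toupper(nt_sequence)
  if (nchar(nt_sequence) == 0L) return("")
  if (grepl("[^ACGT]", nt_sequence))
    stop("coding sequence contains non-ACGT symbols")
  if (nchar(nt_sequence) %% 3L != 0L)
    stop("coding sequence length must be divisible by 3")
  codons <- codon_split(nt_sequence)
  aa <- unname(code[codons])
  stops <- which(aa == "*")
  if (length(stops) > 0L) {
    if (length(stops) > 1L || stops[1] != length(aa))
      stop(sprintf("internal stop codon at codon position %d", stops[1]))
    aa <- aa[-length(aa)]
  }
  paste(aa, collapse = "")
}

#' Split a nucleotide string into codons
#'
#' @param nt_sequence nucleotide string, length divisible by 3.
#' @return character vector of trinucleotides.
#' @export
codon_split <- function(nt_sequence) {
  n <- nchar(nt_sequence)
  if (n %% 3L != 0L) stop("length must be divisible by 3")
  if (n == 0L) return(character(0))
  substring(nt_sequence, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Enumerate synonymous codon pairs (and self-pairs)
#'
#' All unordered pairs of distinct codons within each synonymous group of the
#' genetic code, optionally together with each codon's self-pair (the
#' controls). The standard code yields 87 synonymous pairs and 61 self-pairs.
#'
#' @param code genetic code (possibly restricted to a subset of codons).
#' @param include_self include the self-pairs.
#' @return data.frame with columns `amino_acid`, `codon_a`, `codon_b`.
#' @export
synonymous_pairs <- function(code = standard_genetic_code(),
                             include_self = FALSE) {
  code <- code[code != "*"]
  groups <- split(names(code), unname(code))
  out <- lapply(names(groups), function(aa) {
    codons <- sort(groups[[aa]])
    rows <- list()
    if (include_self)
      rows$self <- data.frame(amino_acid = aa, codon_a = codons,
                              codon_b = codons, stringsAsFactors = FALSE)
    if (length(codons) > 1L) {
      cmb <- utils::combn(codons, 2L)
      rows$pair <- data.frame(amino_acid = aa, codon_a = cmb[1, ],
                              codon_b = cmb[2, ], stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Global alignment of two amino-acid sequences
#'
#' Needleman-Wunsch/Gotoh global alignment with affine gaps via
#' `Biostrings::pairwiseAlignment`. Defaults follow the codon-assignment
#' scheme: BLOSUM80 substitution matrix, gap-opening penalty 10, gap
#' extension penalty 0.5 (a length-L gap costs open + L * extend under this
#' implementation's convention). Terminal gaps are penalized like internal
#' ones.
#'
#' @param a,b amino-acid strings (pattern and subject).
#' @param substitution substitution matrix name or matrix (default
#'   "BLOSUM80").
#' @param gap_open,gap_extend positive gap penalties.
#' @return list with `score`, the two gapped `aligned` strings, and
#'   `mapping`: a data.frame of aligned index pairs (`a_pos`, `b_pos`, NA at
#'   gaps) with a `match` flag for identical residues.
#' @export
global_align <- function(a, b, substitution = "BLOSUM80", gap_open = 10,
                         gap_extend = 0.5) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("sequences must be non-empty")
  if (is.character(substitution) && length(substitution) == 1L) {
    e <- new.env()
    utils::data(list = substitution, package = "Biostrings", envir = e)
    substitution <- get(substitution, envir = e)
  }
  bad <- setdiff(strsplit(paste0(a, b), "")[[1]], rownames(substitution))
  if (length(bad) > 0L)
    stop(sprintf("symbol(s) absent from substitution matrix: %s",
                 paste(unique(bad), collapse = ",")))
  al <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = substitution,
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ai <- cumsum(pa != "-"); bi <- cumsum(sa != "-")
  mapping <- data.frame(
    a_pos = ifelse(pa != "-", ai, NA_integer_),
    b_pos = ifelse(sa != "-", bi, NA_integer_),
    match = pa == sa & pa != "-")
  list(score = Biostrings::score(al),
       aligned = c(a = paste(pa, collapse = ""), b = paste(sa, collapse = "")),
       mapping = mapping)
}

#' Assign codons to the residues of a structure chain
#'
#' Each candidate coding sequence is translated and globally aligned to the
#' chain's amino-acid sequence; the codon aligned to each chain residue is
#' collected across all coding sequences. A residue with exactly one distinct
#' codon, matching its amino acid, is assigned that codon; distinct
#' conflicting codons make it `"AMBIGUOUS"` (a conservative exclusion of
#' positions with more than one genetic variant); no aligned codon, or a
#' codon whose translation mismatches the residue, leaves it `"UNASSIGNED"`.
#'
#' @param chain_sequence the chain's amino-acid string.
#' @param coding_sequences character vector of candidate nucleotide coding
#'   sequences (untranslatable ones are skipped with a warning).
#' @param code genetic code.
#' @param ... passed to [global_align()].
#' @return data.frame with columns `residue_index`, `amino_acid`, `codon`.
#' @export
assign_codons <- function(chain_sequence, coding_sequences,
                          code = standard_genetic_code(), ...) {
  if (length(coding_sequences) == 0L)
    stop("at least one coding sequence is required")
  n <- nchar(chain_sequence)
  chain_aa <- strsplit(chain_sequence, "")[[1]]
  per_residue <- vector("list", n)
  used <- 0L
  for (cds in coding_sequences) {
    aa_seq <- tryCatch(translate_cds(cds, code), error = function(e) {
      warning(sprintf("skipping coding sequence: %s", conditionMessage(e)))
      NULL
    })
    if (is.null(aa_seq) || nchar(aa_seq) == 0L) next
    used <- used + 1L
    codons <- codon_split(cds)[seq_len(nchar(aa_seq))]
    al <- global_align(aa_seq, chain_sequence, ...)
    m <- al$mapping
    hit <- !is.na(m$a_pos) & !is.na(m$b_pos)
    for (r in which(hit)) {
      res <- m$b_pos[r]
      per_residue[[res]] <- c(per_residue[[res]], codons[m$a_pos[r]])
    }
  }
  if (used == 0L) stop("no usable coding sequence")
  codon <- vapply(seq_len(n), function(i) {
    cs <- unique(per_residue[[i]])
    if (length(cs) == 0L) return("UNASSIGNED")
    if (length(cs) > 1L) return("AMBIGUOUS")
    # mismatch guard: the assigned codon must encode the chain's residue
    if (!identical(unname(code[cs]), chain_aa[i])) return("UNASSIGNED")
    cs
  }, character(1))
  data.frame(residue_index = seq_len(n), amino_acid = chain_aa, codon = codon,
             stringsAsFactors = FALSE)
}
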