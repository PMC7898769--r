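#' CpG density of a sequence
#'
#' Number of CpG dinucleotides divided by the sequence length in base pairs.
#' (CG occurrences cannot overlap, so plain match counting is exact.)
#'
#' @param sequence character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return numeric vector of densities, one per sequence.
#' @examples
#' cpg_density(c("CGCGCG", "AAAA", "ACGT"))  # 0.5, 0, 0.25
#' @export
cpg_density <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  if (any(!nzchar(sequence)) || any(is.na(sequence))) {
    stop("cpg_density: empty sequence")
  }
  hits <- gregexpr("CG", sequence, fixed = TRUE)
  n <- vapply(hits, function(m) if (m[1] == -1L) 0L else length(m), integer(1))
  n / nchar(sequence)
}

## genome accessor: accepts a Biostrings::DNAStringSet or a named character
## vector; returns the chromosome as a plain upper-case string
genome_chrom <- function(genome, chrom) {
  if (methods::is(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome)) stop("chromosome '", chrom,
                                        "' absent from genome")
    return(as.character(genome[[chrom]]))
  }
  if (!chrom %in% names(genome)) stop("chromosome '", chrom,
                                      "' absent from genome")
  toupper(genome[[chrom]])
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract an LTR sequence in element orientation
#'
#' Returns the sequence of the element's 5' or 3' LTR, reverse-complemented
#' for minus-strand elements so the result reads 5' to 3' in element
#' orientation.  The "5' LTR" is the LTR at the element's 5' end in element
#' orientation; for a solo LTR the single LTR is the 5' LTR.  Coordinates are
#' 0-based half-open.
#'
#' @param catalogue an `rm_catalogue`.
#' @param element_id element ID (matched against the element table).
#' @param which `"five_prime"` or `"three_prime"`.
#' @param genome a `Biostrings::DNAStringSet` or named character vector of
#'   chromosome sequences.
#' @return a single character string.
#' @export
extract_ltr_sequence <- function(catalogue, element_id,
                                 which = c("five_prime", "three_prime"),
                                 genome) {
  which <- match.arg(which)
  stopifnot(inherits(catalogue, "rm_catalogue"))
  el <- catalogue$elements
  hit <- which(el$element_id == element_id)
  if (length(hit) != 1L) stop("element_id ", element_id,
                              " matches ", length(hit), " elements")
  e <- el[hit, ]
  f <- catalogue$features[catalogue$features$.elem == e$elem, , drop = FALSE]
  f <- f[order(f$start), , drop = FALSE]
  if (e$strand == "-") f <- f[rev(seq_len(nrow(f))), , drop = FALSE]  # 5' first
  role <- subelement_role(f$rep_name, catalogue$registry)
  if (e$structure == "SOLO_LTR") {
    if (which == "three_prime") {
      stop("solo LTR element ", element_id, " has only a 5' LTR")
    }
    ltr <- f[1, ]
  } else {
    pick <- if (which == "five_prime") 1L else nrow(f)
    if (role[pick] != "ltr") {
      stop("element ", element_id, " has no ",
           sub("_", " ", which), " LTR (structure ", e$structure, ")")
    }
    ltr <- f[pick, ]
  }
  chromseq <- genome_chrom(genome, e$chrom)
  s <- substr(chromseq, ltr$start + 1L, ltr$end)  # 0-based half-open -> R 1-based
  if (e$strand == "-") s <- revcomp(s)
  s
}

#' Extract all available 5' LTR sequences of a catalogue
#'
#' Convenience wrapper for the k-mer stage: returns the oriented 5' LTR
#' sequence of every element that has one (solo LTRs included); elements
#' without an annotated 5' LTR are skipped.
#'
#' @param catalogue an `rm_catalogue`.
#' @param genome genome sequences (see [extract_ltr_sequence()]).
#' @param element_ids optional subset of element IDs.
#' @return named character vector (names are element IDs).
#' @export
five_prime_ltr_sequences <- function(catalogue, genome, element_ids = NULL) {
  el <- catalogue$elements
  if (!is.null(element_ids)) el <- el[el$element_id %in% element_ids, ,
                                      drop = FALSE]
  out <- character(0)
  for (id in el$element_id) {
    s <- tryCatch(extract_ltr_sequence(catalogue, id, "five_prime", genome),
                  error = function(e) NULL)
    if (!is.null(s)) out[[as.character(id)]] <- s
  }
  out
}

#' Locate CpG sites in a genome
#'
#' @param genome a `Biostrings::DNAStringSet` or named character vector.
#' @return named list, per chromosome, of 0-based positions of the
#'   plus-strand C of each CpG dyad.
#' @export
find_cpg_sites <- function(genome) {
  chroms <- names(genome)
  out <- lapply(chroms, function(ch) {
    s <- genome_chrom(genome, ch)
    m <- gregexpr("CG", s, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m) - 1L
  })
  stats::setNames(out, chroms)
}
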