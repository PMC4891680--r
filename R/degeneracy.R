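# Codon degeneracy classification and CpG context flags.

#' Degeneracy class labels
#'
#' Order matters: "ambiguous" is reserved for genomic positions assigned
#' conflicting classes by overlapping genes and is excluded from every
#' downstream denominator.
#' @export
DEGENERACY_LEVELS <- c("zero", "two_three", "four", "ambiguous")

.BASES <- c("A", "C", "G", "T")

# cache: one degeneracy lookup table per genetic code (keyed by its contents)
.deg_cache <- new.env(parent = emptyenv())

#' Degeneracy lookup table for a genetic code
#'
#' For every sense codon and codon position, counts how many of the three
#' single-base alternatives preserve the encoded amino acid. A position is
#' zero-fold degenerate if every change is nonsynonymous (substitutions that
#' create a stop codon count as amino-acid-changing), four-fold if every
#' change is synonymous, and two-/three-fold otherwise.
#'
#' @param genetic_code named character vector mapping codons to one-letter
#'   amino acids, stops coded "*" (default the standard code).
#' @return 64 x 3 character matrix of classes ("zero", "two_three", "four"),
#'   rows named by codon; stop-codon rows are NA.
#' @export
degeneracy_table <- function(genetic_code = Biostrings::GENETIC_CODE) {
  key <- paste(names(genetic_code), genetic_code, collapse = "|")
  hit <- .deg_cache[[key]]
  if (!is.null(hit)) return(hit)
  codons <- names(genetic_code)
  tab <- matrix(NA_character_, nrow = length(codons), ncol = 3,
                dimnames = list(codons, NULL))
  for (codon in codons) {
    aa <- genetic_code[[codon]]
    if (aa == "*") next
    for (pos in 0:2) {
      ref <- substr(codon, pos + 1, pos + 1)
      alt <- .BASES[.BASES != ref]
      mut_aa <- vapply(alt, function(b) {
        x <- codon
        substr(x, pos + 1, pos + 1) <- b
        genetic_code[[x]]
      }, character(1))
      n_syn <- sum(mut_aa == aa)  # stop "*" never equals a sense aa
      tab[codon, pos + 1] <-
        if (n_syn == 0L) "zero" else if (n_syn == 3L) "four" else "two_three"
    }
  }
  .deg_cache[[key]] <- tab
  tab
}

#' Classify the degeneracy of a codon position
#'
#' @param codon character vector of 3-mers (sense codons, ACGT alphabet).
#' @param codon_pos integer vector in 0:2 (position within the codon).
#' @param genetic_code codon-to-amino-acid table, see [degeneracy_table()].
#' @return character vector with values "zero", "two_three" or "four".
#' @examples
#' classify_degeneracy("GCT", 2)  # "four": alanine third position
#' classify_degeneracy("ATG", 2)  # "zero": Met has a unique codon
#' @export
classify_degeneracy <- function(codon, codon_pos,
                                genetic_code = Biostrings::GENETIC_CODE) {
  codon <- toupper(as.character(codon))
  if (any(!codon %in% names(genetic_code)) || any(grepl("[^ACGT]", codon)))
    stop("codons must be ACGT 3-mers of the given genetic code")
  if (any(genetic_code[codon] == "*"))
    stop("stop codons have no defined degeneracy")
  if (any(!codon_pos %in% 0:2)) stop("codon_pos must be in 0:2")
  tab <- degeneracy_table(genetic_code)
  n <- max(length(codon), length(codon_pos))
  codon <- rep_len(codon, n)
  codon_pos <- rep_len(codon_pos, n)
  tab[cbind(match(codon, rownames(tab)), codon_pos + 1L)]
}

#' Flag positions participating in a CpG dinucleotide
#'
#' TRUE iff the base at `position` is the C of a CG dinucleotide or the G
#' preceded by a C in the given reference sequence. The flag is symmetric
#' under reverse complement (a CG on one strand is a CG on the other), so it
#' can be computed on the reference forward strand regardless of gene strand.
#'
#' @param sequence a single reference sequence (character or DNAString).
#' @param position 0-based position(s) within the sequence.
#' @return logical vector.
#' @examples
#' flag_cpg("ACGT", 1)  # TRUE, the C of CG
#' flag_cpg("ACGT", 0)  # FALSE
#' @export
flag_cpg <- function(sequence, position) {
  s <- toupper(as.character(sequence))
  if (length(s) != 1L) stop("`sequence` must be a single sequence")
  n <- nchar(s)
  position <- as.integer(position)
  if (any(position < 0L | position >= n)) stop("position out of range")
  base <- substring(s, position + 1L, position + 1L)
  nxt <- ifelse(position + 1L < n,
                substring(s, position + 2L, position + 2L), "")
  prv <- ifelse(position > 0L, substring(s, position, position), "")
  (base == "C" & nxt == "G") | (base == "G" & prv == "C")
}

# Vectorised CpG flags for many positions on one chromosome, given the raw
# character vector of the chromosome (avoids re-splitting per call).
.cpg_from_chars <- function(chars, pos0) {
  n <- length(chars)
  base <- chars[pos0 + 1L]
  nxt <- ifelse(pos0 + 1L < n, chars[pmin(pos0 + 2L, n)], "")
  prv <- ifelse(pos0 > 0L, chars[pmax(pos0, 1L)], "")
  (base == "C" & nxt == "G") | (base == "G" & prv == "C")
}

.comp <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(.comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
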