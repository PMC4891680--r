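# Orthologous coding-site table: one row per coding base with coordinates in
# both species, codon degeneracy, CpG flags, and a mask flag. This table is
# the site universe every downstream denominator is computed on.

.block_coords <- function(start, end, strand) {
  if (strand == "+") start:(end - 1L) else (end - 1L):start
}

.block_seq <- function(genome, chrom, start, end, strand) {
  if (!chrom %in% names(genome))
    stop("chromosome ", chrom, " not found in genome")
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

.as_genome <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(Biostrings::readDNAStringSet(x))
  if (is.character(x)) return(Biostrings::DNAStringSet(x))
  x
}

#' Build the orthologous coding-site table
#'
#' Walks the colinear CDS blocks of each gene in both genomes and emits one
#' row per coding base, carrying genomic coordinates in both species,
#' reference bases on the coding strand, codon index/position, degeneracy
#' class (from the species-A codon), and CpG flags computed from each
#' species' own reference. Genes whose concatenated CDS length is not a
#' multiple of 3, or whose species-A CDS contains a stop codon, are skipped
#' with a warning. A genomic position covered by more than one gene with
#' conflicting degeneracy is emitted once with degeneracy "ambiguous";
#' ambiguous sites never enter downstream denominators.
#'
#' @param map orthology map of blocks, see [read_orthology_map()].
#' @param genome_A,genome_B DNAStringSet (or FASTA path) per species.
#' @param genetic_code codon table, default the standard code.
#' @return data.frame with columns gene_id, codon_index, codon_pos, chrom_A,
#'   coord_A, strand_A, ref_A, chrom_B, coord_B, strand_B, ref_B, degeneracy,
#'   cpg_A, cpg_B, masked; attribute "skipped_genes" lists skipped gene ids.
#' @export
build_site_table <- function(map, genome_A, genome_B,
                             genetic_code = Biostrings::GENETIC_CODE) {
  validate_orthology_map(map)
  genome_A <- .as_genome(genome_A)
  genome_B <- .as_genome(genome_B)
  if (nrow(map) == 0L) return(.empty_site_table())
  tab <- degeneracy_table(genetic_code)
  gene_ids <- unique(map$gene_id)
  skipped <- character(0)
  per_gene <- vector("list", length(gene_ids))
  for (gi in seq_along(gene_ids)) {
    g <- map[map$gene_id == gene_ids[gi], , drop = FALSE]
    cds_A <- paste(mapply(.block_seq, g$chrom_A, g$start_A, g$end_A, g$strand_A,
                          MoreArgs = list(genome = genome_A)), collapse = "")
    cds_B <- paste(mapply(.block_seq, g$chrom_B, g$start_B, g$end_B, g$strand_B,
                          MoreArgs = list(genome = genome_B)), collapse = "")
    n <- nchar(cds_A)
    if (n %% 3L != 0L) {
      warning("gene ", gene_ids[gi], ": CDS length not a multiple of 3; skipped")
      skipped <- c(skipped, gene_ids[gi])
      next
    }
    codons <- substring(cds_A, seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- genetic_code[codons]
    if (any(is.na(aa)) || any(aa == "*")) {
      warning("gene ", gene_ids[gi], ": stop codon or non-ACGT base in CDS; skipped")
      skipped <- c(skipped, gene_ids[gi])
      next
    }
    coord_A <- unlist(mapply(.block_coords, g$start_A, g$end_A, g$strand_A,
                             SIMPLIFY = FALSE), use.names = FALSE)
    coord_B <- unlist(mapply(.block_coords, g$start_B, g$end_B, g$strand_B,
                             SIMPLIFY = FALSE), use.names = FALSE)
    chrom_A <- rep(g$chrom_A, g$end_A - g$start_A)
    chrom_B <- rep(g$chrom_B, g$end_B - g$start_B)
    strand_A <- rep(g$strand_A, g$end_A - g$start_A)
    strand_B <- rep(g$strand_B, g$end_B - g$start_B)
    idx <- seq_len(n) - 1L
    per_gene[[gi]] <- data.frame(
      gene_id = gene_ids[gi],
      codon_index = idx %/% 3L,
      codon_pos = idx %% 3L,
      chrom_A = chrom_A, coord_A = coord_A, strand_A = strand_A,
      ref_A = strsplit(cds_A, "")[[1]],
      chrom_B = chrom_B, coord_B = coord_B, strand_B = strand_B,
      ref_B = strsplit(cds_B, "")[[1]],
      degeneracy = tab[cbind(match(rep(codons, each = 3L), rownames(tab)),
                             idx %% 3L + 1L)],
      stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, per_gene)
  if (is.null(sites)) return(structure(.empty_site_table(), skipped_genes = skipped))
  # CpG flags from each species' own reference, on the reference forward
  # strand (the CG dinucleotide is strand-symmetric)
  sites$cpg_A <- .cpg_flags(genome_A, sites$chrom_A, sites$coord_A)
  sites$cpg_B <- .cpg_flags(genome_B, sites$chrom_B, sites$coord_B)
  # conflicting degeneracy at the same species-A genomic position -> ambiguous
  key <- paste(sites$chrom_A, sites$coord_A)
  if (anyDuplicated(key)) {
    cls <- split(sites$degeneracy, key)
    conflict <- names(cls)[vapply(cls, function(x) length(unique(x)) > 1L, TRUE)]
    sites$degeneracy[key %in% conflict] <- "ambiguous"
    sites <- sites[!duplicated(key), , drop = FALSE]
  }
  sites$masked <- FALSE
  rownames(sites) <- NULL
  attr(sites, "skipped_genes") <- skipped
  sites
}

.cpg_flags <- function(genome, chrom, pos0) {
  out <- logical(length(pos0))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    chars <- strsplit(as.character(genome[[ch]]), "")[[1]]
    out[sel] <- .cpg_from_chars(chars, pos0[sel])
  }
  out
}

.empty_site_table <- function() {
  data.frame(gene_id = character(0), codon_index = integer(0),
             codon_pos = integer(0), chrom_A = character(0),
             coord_A = integer(0), strand_A = character(0),
             ref_A = character(0), chrom_B = character(0),
             coord_B = integer(0), strand_B = character(0),
             ref_B = character(0), degeneracy = character(0),
             cpg_A = logical(0), cpg_B = logical(0), masked = logical(0),
             stringsAsFactors = FALSE)
}

#' Apply per-species exclusion masks to a site table
#'
#' A site is masked iff its species-A coordinate falls in a mask-A interval
#' or its species-B coordinate falls in a mask-B interval. Masked sites are
#' excluded from every downstream denominator; masking is idempotent and
#' accumulates across calls.
#'
#' @param sites site table from [build_site_table()].
#' @param mask_A,mask_B data.frame(chrom, start, end), 0-based half-open
#'   intervals (e.g. from [read_bed()]); NULL for no mask.
#' @return the site table with the masked flag updated.
#' @export
apply_masks <- function(sites, mask_A = NULL, mask_B = NULL) {
  hit <- rep(FALSE, nrow(sites))
  if (!is.null(mask_A) && nrow(mask_A))
    hit <- hit | .in_intervals(sites$chrom_A, sites$coord_A, mask_A)
  if (!is.null(mask_B) && nrow(mask_B))
    hit <- hit | .in_intervals(sites$chrom_B, sites$coord_B, mask_B)
  sites$masked <- sites$masked | hit
  sites
}

.in_intervals <- function(chrom, pos0, intervals) {
  out <- rep(FALSE, length(pos0))
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    if (!any(sel)) next
    ir <- IRanges::IRanges(iv$start + 1L, iv$end)      # half-open -> closed
    q <- IRanges::IRanges(pos0[sel] + 1L, pos0[sel] + 1L)
    out[sel] <- IRanges::overlapsAny(q, ir)
  }
  out
}
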