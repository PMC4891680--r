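# Readers and writers for the standard formats consumed by the pipeline:
# FASTA (Biostrings), VCF (vcfR in, plain-text out), BED masks, and the TSV
# orthology map of colinear equal-length CDS blocks.

.ORTHOLOGY_COLS <- c("gene_id", "chrom_A", "start_A", "end_A", "strand_A",
                     "chrom_B", "start_B", "end_B", "strand_B")

#' Read a TSV orthology map of colinear coding blocks
#'
#' Each row is one CDS block present indel-free in both species; coordinates
#' are 0-based half-open. Blocks of one gene must be listed in transcription
#' order (5' to 3' of the coding sequence) and have equal length in the two
#' species.
#'
#' @param path TSV file with columns gene_id, chrom_A, start_A, end_A,
#'   strand_A, chrom_B, start_B, end_B, strand_B.
#' @return data.frame of validated blocks.
#' @export
read_orthology_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_orthology_map(map)
}

#' Validate an in-memory orthology map
#' @param map data.frame with the columns of [read_orthology_map()].
#' @return the map, invisibly checked.
#' @export
validate_orthology_map <- function(map) {
  miss <- setdiff(.ORTHOLOGY_COLS, names(map))
  if (length(miss))
    stop("orthology map lacks columns: ", paste(miss, collapse = ", "))
  if (any(!map$strand_A %in% c("+", "-")) || any(!map$strand_B %in% c("+", "-")))
    stop("strands must be '+' or '-'")
  len_A <- map$end_A - map$start_A
  len_B <- map$end_B - map$start_B
  if (any(len_A <= 0) || any(len_B <= 0)) stop("blocks must have positive length")
  if (any(len_A != len_B))
    stop("orthologous blocks must have equal length in the two species (indel-free)")
  # non-overlap within each gene, per species
  for (g in split(map, map$gene_id)) {
    for (sp in c("A", "B")) {
      s <- sort(g[[paste0("start_", sp)]])
      e <- sort(g[[paste0("end_", sp)]])
      if (nrow(g) > 1 && any(s[-1] < e[-nrow(g)]))
        stop("overlapping blocks within gene ", g$gene_id[1], " (species ", sp, ")")
    }
  }
  map
}

#' Write an orthology map to TSV
#' @param map block data.frame.
#' @param path output path.
#' @export
write_orthology_map <- function(map, path) {
  utils::write.table(map[, .ORTHOLOGY_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED file of exclusion intervals
#'
#' @param path BED3 file (chrom, start, end; 0-based half-open, no header).
#' @return data.frame with columns chrom, start, end.
#' @export
read_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("BED file needs at least 3 columns")
  bed <- bed[, 1:3]
  names(bed) <- c("chrom", "start", "end")
  bed$start <- as.integer(bed$start)
  bed$end <- as.integer(bed$end)
  if (any(bed$end <= bed$start)) stop("BED intervals must be half-open with end > start")
  bed
}

#' Read biallelic SNVs from a VCF
#'
#' Keeps biallelic single-nucleotide records; multiallelic or non-SNV records
#' are counted and dropped (totals in attribute "dropped"). Positions are
#' converted to the package's 0-based convention. The minor allele frequency
#' is taken from the INFO AF field when present (maf = min(AF, 1 - AF)),
#' otherwise computed from GT sample columns, otherwise NA.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return data.frame with columns chrom, pos (0-based), ref, alt, maf;
#'   attribute "dropped" counts skipped records and attribute
#'   "multiallelic_pos" lists multiallelic positions so downstream code can
#'   drop those sites from denominators.
#' @export
read_snp_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  alt <- fix$ALT
  ref <- fix$REF
  multi <- grepl(",", alt)
  snv <- nchar(ref) == 1L & nchar(alt) == 1L & !multi &
    ref %in% .BASES & alt %in% .BASES
  dropped <- c(multiallelic = sum(multi), non_snv = sum(!snv & !multi))
  if (any(!snv))
    warning(sum(!snv), " non-biallelic-SNV records dropped")
  af <- suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = "AF", as.numeric = TRUE)))
  if (all(is.na(af)) && ncol(v@gt) > 1) {
    gt <- vcfR::extract.gt(v, element = "GT")
    cnt <- function(x) {
      a <- unlist(strsplit(gsub("\\|", "/", x), "/"))
      a <- a[a %in% c("0", "1")]
      c(sum(a == "1"), length(a))
    }
    m <- t(apply(gt, 1, function(r) {
      s <- vapply(r, cnt, numeric(2))
      c(sum(s[1, ]), sum(s[2, ]))
    }))
    af <- ifelse(m[, 2] > 0, m[, 1] / m[, 2], NA_real_)
  }
  out <- data.frame(chrom = fix$CHROM,
                    pos = as.integer(fix$POS) - 1L,
                    ref = ref, alt = alt,
                    maf = pmin(af, 1 - af),
                    stringsAsFactors = FALSE)[snv, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  # multiallelic positions are handed downstream so the whole site can be
  # excluded from denominators (the pattern machinery assumes dimorphism)
  attr(out, "multiallelic_pos") <- data.frame(
    chrom = fix$CHROM[multi], pos = as.integer(fix$POS[multi]) - 1L,
    stringsAsFactors = FALSE)
  out
}

#' Write biallelic SNVs to a plain-text VCF
#'
#' Minimal VCFv4.2 with the allele frequency in INFO AF (frequency of the
#' alternate allele; set from maf assuming the reference allele is major).
#'
#' @param variants data.frame with chrom, pos (0-based), ref, alt, maf.
#' @param path output path (uncompressed .vcf).
#' @param contigs optional named integer vector of contig lengths for the header.
#' @export
write_snp_vcf <- function(variants, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=cosnpr",
           '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele Frequency">')
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contigs), as.integer(contigs)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT",
                        "QUAL", "FILTER", "INFO"), collapse = "\t"))
  ord <- order(variants$chrom, variants$pos)
  v <- variants[ord, , drop = FALSE]
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.6g",
                  v$chrom, v$pos + 1L, v$ref, v$alt, v$maf)
  writeLines(c(hdr, body), path)
  invisible(path)
}
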