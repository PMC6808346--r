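# PLINK 1 binary genotype IO.
#
# BED v1.00: magic bytes 0x6c 0x1b, mode byte 0x01 (SNP-major). Each SNP
# occupies ceiling(n/4) bytes; samples are packed two bits each from the
# least-significant bit pair upwards: 00 = homozygous for the BIM's first
# allele (the counted/effect allele, dosage 2), 10 = heterozygous (1),
# 11 = homozygous other (0), 01 = missing.

# per-byte decode table: 256 x 4 matrix of dosages in sample order
.bed_decode_table <- local({
  code_to_dosage <- c(2L, NA_integer_, 1L, 0L)  # two-bit codes 00,01,10,11
  tab <- matrix(NA_integer_, 256, 4)
  for (b in 0:255) {
    v <- b
    for (pos in 1:4) {
      tab[b + 1, pos] <- code_to_dosage[v %% 4 + 1]
      v <- v %/% 4
    }
  }
  tab
})

#' Read a PLINK binary fileset
#'
#' @param prefix Path stem, or explicit paths via `bed`, `bim`, `fam`.
#' @param bed,bim,fam Optional explicit file paths overriding `prefix`.
#' @return A `genotype_dataset`; the BIM's first allele (a1) is the counted
#'   effect allele.
#' @export
read_plink <- function(prefix = NULL, bed = NULL, bim = NULL, fam = NULL) {
  bed <- bed %||% paste0(prefix, ".bed")
  bim <- bim %||% paste0(prefix, ".bim")
  fam <- fam %||% paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f))
    stop_config("PLINK file not found: %s", f)
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("chr", "snp", "cm", "bp",
                                            "a1", "a2"))
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("fid", "iid", "pat", "mat",
                                            "sex", "pheno"))
  n <- nrow(fam_df)
  m <- nrow(bim_df)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop_config("%s: bad magic bytes; not a PLINK v1 BED file", bed)
  if (raw[3] != as.raw(0x01))
    stop_config("%s: only SNP-major BED files are supported", bed)
  bpv <- ceiling(n / 4)
  if (length(raw) - 3 != bpv * m)
    stop_config("%s: %d data bytes but %d expected for %d individuals x %d SNPs",
                bed, length(raw) - 3, bpv * m, n, m)
  idx <- as.integer(raw[-(1:3)]) + 1L
  # decode all bytes at once, then drop per-SNP padding samples
  dec <- .bed_decode_table[idx, , drop = FALSE]       # (bpv*m) x 4
  full <- matrix(t(dec), nrow = 4 * bpv)              # (4*bpv) x m
  dosage <- full[seq_len(n), , drop = FALSE]
  variants <- bim_df[, c("snp", "chr", "bp", "a1", "a2")]
  if (anyDuplicated(variants$snp))
    stop_config("%s: duplicate variant identifiers", bim)
  colnames(dosage) <- variants$snp
  samples <- fam_df[, c("fid", "iid", "sex")]
  rownames(dosage) <- samples$iid
  genotype_dataset(dosage, variants, samples)
}

#' Assign gene labels from configured gene regions
#'
#' Labels each variant with the gene whose region (closed interval on the
#' same chromosome) contains its position; variants outside every region
#' get NA.
#'
#' @param dataset A `genotype_dataset`.
#' @param regions data.frame with columns gene, chr, start, end (default
#'   [default_gene_blocks()]).
#' @return The dataset with a `gene` column on its variant table.
#' @export
assign_genes <- function(dataset, regions = default_gene_blocks()) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  v <- dataset$variants
  gene <- rep(NA_character_, nrow(v))
  for (i in seq_len(nrow(regions))) {
    hit <- v$chr == regions$chr[i] & v$bp >= regions$start[i] &
      v$bp <= regions$end[i]
    gene[hit] <- regions$gene[i]
  }
  dataset$variants$gene <- gene
  dataset
}

#' Write a genotype dataset as a PLINK binary fileset
#'
#' @param dataset A `genotype_dataset`.
#' @param prefix Output path stem; writes `<prefix>.bed/.bim/.fam`.
#' @return Invisibly, the three paths.
#' @export
write_plink <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  g <- dataset$dosage
  n <- nrow(g)
  m <- ncol(g)
  # dosage -> two-bit code: 2->00, 1->10, 0->11, NA->01
  n_pad <- 4 * ceiling(n / 4)
  codes <- matrix(0L, n_pad, m)             # padding bits are zero
  code_of <- c(3L, 2L, 0L)
  codes[seq_len(n), ] <- ifelse(is.na(g), 1L, code_of[g + 1L])
  dim(codes) <- c(4, length(codes) / 4)
  bytes <- as.raw(colSums(codes * c(1L, 4L, 16L, 64L)))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  v <- dataset$variants
  utils::write.table(
    data.frame(v$chr, v$snp, 0, v$bp, v$a1, v$a2),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  s <- dataset$samples
  utils::write.table(
    data.frame(s$fid, s$iid, 0, 0, s$sex %||% 0, -9),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}
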