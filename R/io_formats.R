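## Shared containers and readers/writers.
##
## Conventions fixed pipeline-wide:
##   * genomic coordinates are 1-based inclusive;
##   * SNP identifiers are "chr_pos_ref_alt" (as in "2_179378512_T_C");
##   * dosages count copies of the cohort minor allele, determined once at
##     load and frozen in the SNP metadata so stage-I and stage-II codings
##     cannot drift;
##   * TSS = start on the + strand, end on the - strand.

#' Construct a genotype matrix container
#'
#' @param dosage numeric matrix, animals x SNPs, entries 0/1/2 (minor-allele
#'   counts) with `NA` allowed before quality control. Row names are sample
#'   ids, column names SNP ids.
#' @param map data.frame with columns `snp_id`, `chr`, `pos`, `ref`, `alt`,
#'   `minor` (the counted allele), one row per dosage column.
#' @return object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, map) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  check_that(nrow(map) == ncol(dosage),
             "map rows (", nrow(map), ") != dosage columns (", ncol(dosage), ")")
  check_that(!anyDuplicated(map$snp_id), "duplicate SNP ids in map")
  check_that(all(map$pos > 0), "SNP positions must be positive (1-based)")
  rng <- range(dosage, na.rm = TRUE)
  check_that(rng[1] >= 0 && rng[2] <= 2, "dosages must lie in [0, 2]")
  if (is.null(map$minor)) map$minor <- map$alt
  colnames(dosage) <- map$snp_id
  structure(list(dosage = dosage, map = as.data.frame(map)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d animals x %d SNPs (%d chromosome(s), %s missing)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chr)),
              format(sum(is.na(x$dosage)))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

## subset a geno_matrix by SNP index or id (keeps map aligned)
subset_snps <- function(G, j) {
  if (is.character(j)) j <- match(j, G$map$snp_id)
  geno_matrix(G$dosage[, j, drop = FALSE], G$map[j, , drop = FALSE])
}

snp_id_string <- function(chr, pos, ref, alt) paste(chr, pos, ref, alt, sep = "_")

#' Read genotypes from VCF or PLINK .raw-style TSV
#'
#' Dosages count the cohort minor allele: the minor allele is decided from
#' allele frequencies in the file being read and recorded in the `minor`
#' metadata column. Multi-allelic VCF records are skipped with a warning.
#'
#' @param path input file.
#' @param format `"vcf"` (v4.x, GT field) or `"raw"` (header of SNP columns
#'   named `<snp_id>_<counted allele>` after the `IID` column, as written by
#'   [write_genotypes_raw()]).
#' @return [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "raw")) {
  format <- match.arg(format)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_raw(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ## ALT-allele counts; "." / missing -> NA
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(gsub("\\|", "/", g), "/", fixed = TRUE),
                  function(a) sum(a == "1"), numeric(1)))
  }
  alt_dos <- apply(gt, 2, count_alt)
  if (is.null(dim(alt_dos))) alt_dos <- matrix(alt_dos, nrow = 1)
  alt_dos <- t(alt_dos)  # samples x SNPs
  map <- data.frame(snp_id = snp_id_string(fix$CHROM, as.integer(fix$POS),
                                           fix$REF, fix$ALT),
                    chr = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  ## freeze minor allele from this cohort
  p_alt <- colMeans(alt_dos, na.rm = TRUE) / 2
  flip <- !is.na(p_alt) & p_alt > 0.5
  dos <- alt_dos
  dos[, flip] <- 2 - alt_dos[, flip, drop = FALSE]
  map$minor <- ifelse(flip, map$ref, map$alt)
  rownames(dos) <- colnames(gt)
  geno_matrix(dos, map)
}

read_genotypes_raw <- function(path) {
  x <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = c("NA", "")))
  check_that("IID" %in% names(x), "raw genotype table lacks an IID column")
  samp <- as.character(x$IID)
  snpcols <- setdiff(names(x), c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
  dos <- as.matrix(x[, snpcols, drop = FALSE])
  storage.mode(dos) <- "double"
  rownames(dos) <- samp
  ## column name dialect: chr_pos_ref_alt_<counted allele>
  parts <- strsplit(snpcols, "_", fixed = TRUE)
  bad <- lengths(parts) != 5L
  if (any(bad)) stop("malformed .raw SNP column name(s): ",
                     paste(head(snpcols[bad], 3), collapse = ", "))
  map <- data.frame(
    chr = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    ref = vapply(parts, `[`, "", 3L),
    alt = vapply(parts, `[`, "", 4L),
    minor = vapply(parts, `[`, "", 5L),
    stringsAsFactors = FALSE)
  map$snp_id <- snp_id_string(map$chr, map$pos, map$ref, map$alt)
  colnames(dos) <- map$snp_id
  geno_matrix(dos, map[, c("snp_id", "chr", "pos", "ref", "alt", "minor")])
}

#' Write genotypes as a VCF v4.2 file (GT field)
#'
#' GT alleles follow the stored REF/ALT, so a minor allele equal to REF is
#' emitted with the complementary ALT count; a read-back therefore recovers
#' the identical dosage matrix.
#'
#' @param G [geno_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(G, path) {
  map <- G$map
  alt_dos <- G$dosage
  flip <- map$minor == map$ref
  alt_dos[, flip] <- 2 - alt_dos[, flip, drop = FALSE]
  gt_codes <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=bubalusTwas",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(G$dosage)), collapse = "\t")),
             con)
  body <- vapply(seq_len(ncol(alt_dos)), function(j) {
    d <- alt_dos[, j]
    g <- ifelse(is.na(d), "./.", gt_codes[d + 1L])
    paste(c(map$chr[j], map$pos[j], map$snp_id[j], map$ref[j], map$alt[j],
            ".", "PASS", ".", "GT", g), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Write genotypes as a PLINK .raw-style additive dosage TSV
#'
#' @param G [geno_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_raw <- function(G, path) {
  hdr <- paste0(G$map$snp_id, "_", G$map$minor)
  out <- data.frame(FID = rownames(G$dosage), IID = rownames(G$dosage),
                    check.names = FALSE)
  dos <- as.data.frame(G$dosage)
  names(dos) <- hdr
  write_tsv_table(cbind(out, dos), path)
}

#' Read gene models from a GTF file
#'
#' Keeps `gene` features and derives the transcription start site per strand
#' (start on `+`, end on `-`).
#'
#' @param path GTF file.
#' @return data.frame with columns `gene_id`, `chr`, `start`, `end`,
#'   `strand`, `tss` (1-based inclusive coordinates).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0L) stop("no gene features in ", path)
  gid <- gr$gene_id
  if (is.null(gid) || anyNA(gid)) stop("GTF gene feature lacks a gene_id attribute")
  ann <- data.frame(gene_id = as.character(gid),
                    chr = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  check_that(all(ann$strand %in% c("+", "-")),
             "gene strand must be + or - (got unstranded feature)")
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  ann
}

#' Write gene models as a minimal GTF (gene features only)
#'
#' @param genes data.frame as returned by [read_gtf()] (`tss` ignored).
#' @param path output path.
#' @param source source field to print (default `"bubalusTwas"`).
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path, source = "bubalusTwas") {
  lines <- sprintf('%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                   genes$chr, source, genes$start, genes$end,
                   genes$strand, genes$gene_id)
  writeLines(lines, path)
  invisible(path)
}
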