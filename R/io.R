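#' Read a VCF into a genotype matrix
#'
#' Reads diploid biallelic SNP genotypes (GT field) from a VCF v4.2 file.
#' Dosage is the count of alternate alleles; `./.` and half-calls such as
#' `0/.` become missing; the phasing separator (`|` vs `/`) is ignored.
#' Site order is preserved from the file and must already be sorted by
#' `(chrom, pos)` — violations are reported, not repaired.
#'
#' @param path VCF file path (plain text or bgzipped)
#' @param skip_invalid if `TRUE` (default), multiallelic or non-SNP records
#'   are skipped with a warning; if `FALSE` they are an error.
#' @return a [genotype_matrix()]
#' @export
read_vcf <- function(path, skip_invalid = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(vcf@gt)[-1]
  if (is.null(samples)) samples <- character(0)
  if (anyDuplicated(samples))
    stop("duplicate sample names in VCF header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))

  n_rec <- nrow(fix)
  if (n_rec == 0L) {
    return(genotype_matrix(
      matrix(integer(0), nrow = length(samples), ncol = 0),
      data.frame(chrom = character(0), pos = integer(0), id = character(0),
                 ref = character(0), alt = character(0)),
      samples))
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp_ok <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE)
  if (any(!snp_ok)) {
    if (!skip_invalid)
      stop(sum(!snp_ok), " multiallelic or non-SNP record(s) in ", path)
    warning("skipping ", sum(!snp_ok), " multiallelic or non-SNP record(s)")
  }
  gt <- vcf@gt[, -1, drop = FALSE]
  gt <- gt[snp_ok, , drop = FALSE]
  fix <- fix[snp_ok, , drop = FALSE]
  # strip any extra FORMAT fields; GT is always first when present
  gt_field <- sub(":.*$", "", gt)
  dosage <- .gt_to_dosage(gt_field)

  ids <- fix[, "ID"]
  blank <- is.na(ids) | ids == "." | ids == ""
  ids[blank] <- paste0(fix[blank, "CHROM"], "_", fix[blank, "POS"])
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      id = ids,
                      ref = fix[, "REF"],
                      alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  genotype_matrix(t(dosage), sites, samples)
}

# GT strings -> alt-allele dosage; any "." allele makes the call missing
.gt_to_dosage <- function(gt_field) {
  d <- matrix(NA_integer_, nrow = nrow(gt_field), ncol = ncol(gt_field))
  lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  norm <- gsub("|", "/", gt_field, fixed = TRUE)
  hit <- lut[norm]
  d[] <- hit
  unknown <- is.na(hit) & !is.na(norm) & !grepl(".", norm, fixed = TRUE) &
    norm != ""
  if (any(unknown))
    stop("unparseable GT value(s), e.g. ", norm[unknown][1])
  d
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits a minimal GT-only, unphased VCF (`0/0`, `0/1`, `1/1`, `./.`).
#' Output is deterministic and byte-stable for a fixed input, and
#' round-trips through [read_vcf()].
#'
#' @param gm a [genotype_matrix()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_vcf <- function(gm, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (n_sites(gm) > 0L) {
    gt_code <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow = n_sites(gm), ncol = n_samples(gm))
    dt <- t(gm$dosage)
    ok <- !is.na(dt)
    gt[ok] <- gt_code[dt[ok] + 1L]
    lines <- paste(gm$sites$chrom, gm$sites$pos, gm$sites$id,
                   gm$sites$ref, gm$sites$alt, ".", "PASS", ".", "GT",
                   sep = "\t")
    gt_cols <- apply(gt, 1L, paste, collapse = "\t")
    if (n_samples(gm) > 0L) lines <- paste(lines, gt_cols, sep = "\t")
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read a two-column population map
#'
#' Whitespace- or tab-delimited text, one `sample population` pair per line.
#' Lines starting with `#` are ignored.
#'
#' @param path file path
#' @param n_populations required population count (default 2); `NA` to accept
#'   any
#' @return a [population_map()]
#' @export
read_population_map <- function(path, n_populations = 2L) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#",
                           col.names = c("sample", "population"))
  pm <- population_map(tab$sample, tab$population)
  labels <- attr(pm, "labels")
  if (!is.na(n_populations) && length(labels) != n_populations)
    stop("population map has ", length(labels), " populations (",
         paste(labels, collapse = ", "), "); expected ", n_populations)
  pm
}

#' Write a population map
#' @param popmap a [population_map()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_population_map <- function(popmap, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(popmap$sample, popmap$population, sep = "\t"), con)
  invisible(path)
}

#' Read gene annotation from BED or GFF3
#'
#' Normalizes to the package's internal 0-based half-open coordinates:
#' BED records pass through unchanged, GFF3 `gene` records are shifted from
#' 1-based inclusive. Output is sorted by `(chrom, start)`.
#'
#' @param path file path
#' @param format `"bed"` or `"gff3"`; inferred from the extension when `NULL`
#' @return data.frame with columns `chrom`, `start` (0-based inclusive),
#'   `end` (0-based exclusive), `gene_id`, `strand`
#' @export
read_gene_annotation <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "bed"
  }
  format <- match.arg(tolower(format), c("bed", "gff3"))
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    if (length(gr) == 0L) {
      warning("no gene-type records in ", path)
      return(.empty_gene_table())
    }
    ids <- as.character(gr$ID)
    if (all(is.na(ids)) && !is.null(gr$Name)) ids <- as.character(gr$Name)
  } else {
    ids <- if (!is.null(gr$name)) as.character(gr$name) else
      rep(NA_character_, length(gr))
  }
  if (length(gr) == 0L) return(.empty_gene_table())
  blank <- is.na(ids) | ids == ""
  ids[blank] <- paste0("gene_", seq_along(gr)[blank])
  genes <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # GRanges is 1-based inclusive
    end = GenomicRanges::end(gr),
    gene_id = ids,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  genes$strand[genes$strand == "*"] <- "."
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  if (any(genes$start >= genes$end)) stop("gene with start >= end in ", path)
  genes
}

.empty_gene_table <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             gene_id = character(0), strand = character(0),
             stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' @param x data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`/`gene_id`/`direction` for column 4
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_bed <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(x) > 0L) {
    name_col <- intersect(c("name", "direction", "gene_id"), names(x))
    nm <- if (length(name_col) > 0L) as.character(x[[name_col[1]]]) else "."
    writeLines(paste(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                     format(x$end, scientific = FALSE, trim = TRUE), nm,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a gene-set table
#'
#' Two-column TSV `set_id <TAB> gene_id`, one membership per line; `#`
#' comment lines ignored.
#'
#' @param path file path
#' @return named list of character vectors of gene ids
#' @export
read_gene_sets <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#",
                           col.names = c("set_id", "gene_id"))
  split(tab$gene_id, tab$set_id)
}

#' Write a TSV with deterministic formatting
#' @param x data.frame
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_tsv <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(format(x, digits = 10, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
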