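# Reading and writing variant tables, allele-frequency panels, BED tracks
# and gene annotations.  Internal coordinates are 1-based inclusive
# throughout; BED's 0-based half-open convention is converted only at the
# file boundary.  Gzip input is handled transparently by R's connections.

normalize_flag <- function(x) {
  x <- as.character(x)
  x[x %in% c("PASS", "Pass", "pass", ".")] <- "pass"
  x[x %in% c("alleleBias", "allele_bias", "AlleleBias")] <- "allele_bias"
  x
}

#' Read a variant table from VCF or TSV
#'
#' TSV input must carry the canonical columns (`chrom`, `pos`, `ref`,
#' `alt`, `sample_id`, `genotype`, `quality_flag`, `somatic_status`; missing
#' quality/status columns are filled with defaults).  VCF 4.2 input (via
#' \pkg{vcfR}) may be single- or multi-sample; multi-allelic rows are split
#' into biallelic records and records that are not single-nucleotide
#' substitutions are dropped with a message stating how many.
#'
#' @param path File path (optionally gzipped).
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A variant table; rows are per-sample calls with `genotype > 0`.
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "vcf") read_variants_vcf(path) else read_variants_tsv(path)
}

read_variants_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return(empty_variant_table())
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = NA)
  if (nrow(x) == 0L) return(empty_variant_table())
  need <- c("chrom", "pos", "ref", "alt", "sample_id")
  if (!all(need %in% names(x)))
    stop("TSV lacks required columns: ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  x$pos <- suppressWarnings(as.integer(x$pos))
  bad <- which(is.na(x$pos) | x$pos < 1 | is.na(x$ref) | is.na(x$alt))
  if (length(bad))
    stop("malformed variant row at line ", bad[1] + 1L, " of ", path,
         call. = FALSE)
  x$genotype <- as.integer(x$genotype %||% 1L)
  x$quality_flag <- normalize_flag(x$quality_flag %||% "pass")
  x$somatic_status <- as.character(x$somatic_status %||% "unknown")
  x <- x[VARIANT_COLUMNS]
  keep <- is_snv(x)
  if (any(!keep))
    message("read_variants: dropped ", sum(!keep), " non-SNV record(s)")
  x <- x[keep, , drop = FALSE]
  rownames(x) <- NULL
  validate_variants(x)
}

read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix[, 1:7, drop = FALSE], stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty_variant_table())
  gt <- if (ncol(v@gt) > 1L) vcfR::extract.gt(v, element = "GT") else NULL
  if (!is.null(gt)) gt <- matrix(gt, nrow = nrow(fix),
                                 dimnames = dimnames(gt))
  samples <- if (is.null(gt)) "sample1" else colnames(gt)
  somatic <- grepl("SOMATIC", v@fix[, "INFO"])
  rows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (ai in seq_along(alts)) {
      ref <- fix$REF[i]; alt <- alts[ai]
      if (nchar(ref) != 1L || nchar(alt) != 1L ||
          !alt %in% c("A", "C", "G", "T") || ref == alt) {
        dropped <- dropped + 1L
        next
      }
      for (s in samples) {
        gcount <- if (is.null(gt)) 1L else {
          al <- strsplit(gt[i, s] %||% ".", "[/|]")[[1]]
          sum(al == as.character(ai), na.rm = TRUE)
        }
        if (is.na(gcount) || gcount == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
          ref = ref, alt = alt, sample_id = s, genotype = gcount,
          quality_flag = normalize_flag(fix$FILTER[i] %||% "pass"),
          somatic_status = if (isTRUE(somatic[i])) "somatic" else "unknown",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (dropped) message("read_variants: dropped ", dropped, " non-SNV record(s)")
  if (!length(rows)) return(empty_variant_table())
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  validate_variants(out)
}

#' Write a variant table to TSV or VCF 4.2
#'
#' VCF output is multi-sample: one column per `sample_id`, genotype coded
#' `0/1` or `1/1`, caller flag in FILTER (`pass` re-capitalized to `PASS`)
#' and `SOMATIC` in INFO for somatic records.
#'
#' @param x Variant table.
#' @param path Output path; a `.gz` suffix gzips the file.
#' @param format `"auto"`, `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_variants <- function(x, path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  x <- validate_variants(x)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (format == "tsv") {
    write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  samples <- sort(unique(x$sample_id))
  key <- variant_key(x)
  uk <- !duplicated(key)
  vars <- x[uk, c("chrom", "pos", "ref", "alt", "quality_flag",
                  "somatic_status"), drop = FALSE]
  ord <- order(vars$chrom, vars$pos, vars$alt)
  vars <- vars[ord, , drop = FALSE]
  gmat <- matrix("0/0", nrow = nrow(vars), ncol = length(samples),
                 dimnames = list(NULL, samples))
  idx <- match(key, variant_key(vars))
  for (r in seq_len(nrow(x)))
    gmat[idx[r], x$sample_id[r]] <- if (x$genotype[r] >= 2L) "1/1" else "0/1"
  filt <- ifelse(vars$quality_flag == "pass", "PASS", vars$quality_flag)
  info <- ifelse(vars$somatic_status == "somatic", "SOMATIC", ".")
  header <- c("##fileformat=VCFv4.2",
              "##source=regionburden",
              "##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description=\"Somatic mutation\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(vars$chrom, vars$pos, ".", vars$ref, vars$alt, ".", filt,
                info, "GT", apply(gmat, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read an allele-frequency panel
#'
#' Reads a TSV with columns `chrom`, `pos`, `ref`, `alt`, `maf`.  Keys
#' `(chrom, pos, ref, alt)` must be unique and `maf` must lie in
#' \[0, 0.5\].
#'
#' @param path File path.
#' @param provenance Optional label recorded as an attribute.
#' @return `data.frame` of class `allele_frequency_panel`, sorted by
#'   position.
#' @export
read_panel <- function(path, provenance = basename(path)) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "maf")
  if (!all(need %in% names(x)))
    stop("panel lacks columns: ", paste(setdiff(need, names(x)), collapse = ", "),
         call. = FALSE)
  allele_frequency_panel(x, provenance = provenance)
}

#' @rdname read_panel
#' @param x `data.frame` with panel columns.
#' @export
allele_frequency_panel <- function(x, provenance = "panel") {
  if (any(x$maf < 0 | x$maf > 0.5))
    stop("panel MAF outside [0, 0.5]", call. = FALSE)
  k <- paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  if (anyDuplicated(k))
    stop("duplicate panel key: ", k[duplicated(k)][1], call. = FALSE)
  x <- x[order(x$chrom, x$pos, x$alt), , drop = FALSE]
  rownames(x) <- NULL
  attr(x, "provenance") <- provenance
  class(x) <- c("allele_frequency_panel", class(x))
  x
}

#' Read and write BED3 interval tracks
#'
#' BED files are 0-based, half-open; internal intervals are 1-based
#' inclusive, so a BED line `chr3 99 200` becomes the interval
#' `(100, 200)`.  The two conversions are exact inverses.
#'
#' @param path File path.
#' @return `read_bed()`: `data.frame(chrom, start, end[, name])`, 1-based
#'   inclusive, sorted.
#' @export
read_bed <- function(path) {
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  if (length(first) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  x <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4L) names(x)[4] <- "name"
  x$start <- x$start + 1  # 0-based half-open -> 1-based inclusive
  if (any(x$start > x$end)) stop("empty or negative BED interval", call. = FALSE)
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' @rdname read_bed
#' @param x Interval `data.frame(chrom, start, end)` (1-based inclusive).
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  out <- data.frame(chrom = x$chrom, start = format(x$start - 1, scientific = FALSE, trim = TRUE),
                    end = format(x$end, scientific = FALSE, trim = TRUE))
  if (!is.null(x$name)) out$name <- x$name
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' TSV with columns `gene_id`, `chrom`, `tss`, `strand` (`+`/`-`).
#'
#' @param path File path.
#' @return `data.frame` sorted by chromosome and TSS.
#' @export
read_genes <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(x)))
    stop("gene table lacks columns: ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  if (!all(x$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  x <- x[order(x$chrom, x$tss), , drop = FALSE]
  rownames(x) <- NULL
  x
}
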