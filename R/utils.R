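# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the random seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded simulations do not perturb the global
#' random stream.  With `seed = NULL` the expression runs on the current
#' stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Genomic interval (1-based, inclusive)
#'
#' Internal coordinates throughout the package are 1-based and inclusive at
#' both ends, matching the convention in which region boundaries such as
#' `chr3:182,189,714-182,229,714` are printed.  BED input/output converts at
#' the file boundary (see [read_bed()]).
#'
#' @param chrom Chromosome name.
#' @param start,end Interval bounds, `start <= end`, both included.
#' @return An object of class `genomic_interval`: a list with elements
#'   `chrom`, `start`, `end`.
#' @examples
#' genomic_interval("chr3", 182189714, 182229714)
#' parse_region("chr3:182189714-182229714")
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 1 || start > end)
    stop("invalid interval: need 1 <= start <= end", call. = FALSE)
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "genomic_interval")
}

#' @rdname genomic_interval
#' @param x A region string `"chrom:start-end"` (commas allowed).
#' @export
parse_region <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- gsub(",", "", x, fixed = TRUE)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) != 4L) stop("cannot parse region string: ", x, call. = FALSE)
  genomic_interval(m[2], as.numeric(m[3]), as.numeric(m[4]))
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s (%s bp)\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              format(x$end - x$start + 1, big.mark = ",")))
  invisible(x)
}

interval_length <- function(region) region$end - region$start + 1

as_region <- function(x) {
  if (inherits(x, "genomic_interval")) return(x)
  if (is.character(x)) return(parse_region(x))
  if (is.list(x) && all(c("chrom", "start", "end") %in% names(x)))
    return(genomic_interval(x$chrom, x$start, x$end))
  stop("cannot interpret `region`", call. = FALSE)
}

# Canonical variant identity: zygosity is ignored, a variant is its locus
# plus substituted base.
variant_key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")

VARIANT_COLUMNS <- c("chrom", "pos", "ref", "alt", "sample_id", "genotype",
                     "quality_flag", "somatic_status")

empty_variant_table <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), sample_id = character(), genotype = integer(),
             quality_flag = character(), somatic_status = character(),
             stringsAsFactors = FALSE)
}

#' Assemble a variant table
#'
#' Builds the package's canonical single-nucleotide variant table.  One row
#' is one called substitution in one sample.
#'
#' @param chrom,pos,ref,alt Variant locus and alleles (single bases,
#'   `ref != alt`).
#' @param sample_id Sample the call was made in.
#' @param genotype Alternate-allele copy count, 0/1/2.
#' @param quality_flag Caller flag; `"pass"` and `"allele_bias"` pass the
#'   quality gate, anything else is preserved verbatim but fails it.
#' @param somatic_status One of `"somatic"`, `"germline"`, `"unknown"`.
#' @return A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`, `genotype`, `quality_flag`, `somatic_status`.
#' @export
variant_table <- function(chrom, pos, ref, alt, sample_id,
                          genotype = 1L, quality_flag = "pass",
                          somatic_status = "unknown") {
  n <- length(pos)
  out <- data.frame(chrom = rep_len(as.character(chrom), n),
                    pos = as.integer(pos),
                    ref = rep_len(as.character(ref), n),
                    alt = rep_len(as.character(alt), n),
                    sample_id = rep_len(as.character(sample_id), n),
                    genotype = rep_len(as.integer(genotype), n),
                    quality_flag = rep_len(as.character(quality_flag), n),
                    somatic_status = rep_len(as.character(somatic_status), n),
                    stringsAsFactors = FALSE)
  validate_variants(out)
}

validate_variants <- function(x, allow_non_snv = FALSE) {
  if (!is.data.frame(x)) stop("variant table must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(VARIANT_COLUMNS, names(x))
  if (length(missing_cols))
    stop("variant table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(x) == 0L) return(x)
  if (any(x$pos < 1, na.rm = TRUE)) stop("positions must be >= 1", call. = FALSE)
  if (!allow_non_snv) {
    bad <- nchar(x$ref) != 1L | nchar(x$alt) != 1L | x$ref == x$alt
    if (any(bad))
      stop(sum(bad), " record(s) are not single-nucleotide substitutions",
           call. = FALSE)
  }
  x
}

is_snv <- function(x) {
  nchar(x$ref) == 1L & nchar(x$alt) == 1L &
    x$ref %in% c("A", "C", "G", "T") & x$alt %in% c("A", "C", "G", "T") &
    x$ref != x$alt
}

# Random ref/alt base pairs, guaranteed ref != alt.
random_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- sample(bases[-1L], n, replace = TRUE)  # offset trick below
  # draw alt uniformly from the three bases != ref
  shift <- sample.int(3L, n, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
  list(ref = ref, alt = alt)
}
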