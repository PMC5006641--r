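# Ancestor ("root") variant discovery: variants shared by essentially all
# microdissected tumor islets and absent from the matched normal are the
# candidate early driver mutations that predate clonal divergence.

#' Configuration of the ancestor-variant call
#'
#' @param islet_presence_threshold Minimum fraction of islets that must
#'   carry a variant, compared inclusively (`>=`); the discovery rule is
#'   90%.
#' @param require_absent_in_normal Drop variants also called in the matched
#'   normal (germline exclusion).
#' @return A list of class `ancestor_call_config`.
#' @export
ancestor_call_config <- function(islet_presence_threshold = 0.90,
                                 require_absent_in_normal = TRUE) {
  if (islet_presence_threshold <= 0 || islet_presence_threshold > 1)
    stop("islet_presence_threshold must lie in (0, 1]", call. = FALSE)
  structure(list(islet_presence_threshold = islet_presence_threshold,
                 require_absent_in_normal = isTRUE(require_absent_in_normal)),
            class = "ancestor_call_config")
}

#' Variant-by-islet presence matrix
#'
#' @param islet_tables List of per-islet variant tables.
#' @return Logical matrix, one row per distinct variant (named by
#'   `chrom:pos:ref:alt` key), one column per islet.  Row sums are carrier
#'   counts; column sums are per-islet variant counts.
#' @export
presence_matrix <- function(islet_tables) {
  if (length(islet_tables) == 0L) stop("zero islets", call. = FALSE)
  islet_tables <- lapply(islet_tables, validate_variants)
  keys <- lapply(islet_tables, variant_key)
  all_keys <- sort(unique(unlist(keys)))
  m <- vapply(keys, function(k) all_keys %in% k,
              logical(length(all_keys)))
  m <- matrix(m, nrow = length(all_keys),
              dimnames = list(all_keys,
                              names(islet_tables) %||%
                                paste0("islet", seq_along(islet_tables))))
  m
}

#' Identify ancestor variants shared across tumor islets
#'
#' A variant is an ancestor candidate when its exact islet-presence
#' fraction (carriers / islets) is at least the configured threshold and,
#' if a matched normal is supplied, it was not called in the normal.
#' Variant identity is `(chrom, pos, ref, alt)`; genotype zygosity is
#' ignored because islet calls are sparse.
#'
#' @param islet_tables List of >= 2 per-islet variant tables.
#' @param normal_table Matched-normal variant table, or `NULL`.
#' @param config An [ancestor_call_config()].
#' @return Variant-level `data.frame` (`chrom`, `pos`, `ref`, `alt`,
#'   `n_islets_carrying`, `presence_fraction`) of the retained variants,
#'   sorted by position.  The full per-variant fraction table is attached
#'   as attribute `"all_fractions"`.
#' @export
identify_ancestor_variants <- function(islet_tables, normal_table = NULL,
                                       config = ancestor_call_config()) {
  if (length(islet_tables) < 2L)
    stop("need at least 2 islet call sets", call. = FALSE)
  stopifnot(inherits(config, "ancestor_call_config"))
  pm <- presence_matrix(islet_tables)
  carriers <- rowSums(pm)
  frac <- carriers / ncol(pm)
  combined <- do.call(rbind, lapply(islet_tables, function(t)
    t[c("chrom", "pos", "ref", "alt")]))
  combined <- combined[!duplicated(variant_key(combined)), , drop = FALSE]
  idx <- match(rownames(pm), variant_key(combined))
  out <- combined[idx, , drop = FALSE]
  out$n_islets_carrying <- as.integer(carriers)
  out$presence_fraction <- frac
  keep <- frac >= config$islet_presence_threshold
  if (config$require_absent_in_normal && !is.null(normal_table)) {
    normal_keys <- variant_key(validate_variants(normal_table))
    keep <- keep & !(rownames(pm) %in% normal_keys)
  }
  res <- out[keep, , drop = FALSE]
  res <- res[order(res$chrom, res$pos, res$alt), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "all_fractions") <- out
  attr(res, "n_islets") <- ncol(pm)
  res
}
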