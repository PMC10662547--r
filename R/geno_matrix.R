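#' Genotype matrix container
#'
#' A `geno_matrix` holds diploid biallelic genotypes for a set of samples as
#' a three-valued code: `0` = reference homozygote, `1` = alternate
#' homozygote, `NA` = missing. Heterozygous calls never appear; they are
#' masked to missing when a VCF is ingested. Marker metadata (id,
#' chromosome, 1-based position, REF and ALT alleles) travels with the
#' matrix and markers are kept sorted by chromosome (in order of first
#' appearance) and position.
#'
#' @param geno integer matrix, samples in rows, markers in columns; entries
#'   in `{0, 1, NA}`.
#' @param markers data.frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt`; one row per column of `geno`.
#' @param samples character vector of sample labels (defaults to the
#'   rownames of `geno`).
#' @param note free-text provenance note.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, markers, samples = rownames(geno), note = "") {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(samples)) stop_validation("sample labels are required")
  samples <- as.character(samples)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(markers)))
    stop_validation("marker table must have columns: %s", paste(need, collapse = ", "))
  markers$pos <- as.integer(markers$pos)
  if (nrow(markers) != ncol(geno))
    stop_validation("marker table has %d rows but genotype matrix has %d columns",
                    nrow(markers), ncol(geno))
  if (length(samples) != nrow(geno))
    stop_validation("%d sample labels for %d genotype rows",
                    length(samples), nrow(geno))
  if (anyDuplicated(samples))
    stop_validation("duplicate sample labels: %s",
                    paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyDuplicated(markers$id))
    stop_validation("duplicate marker ids: %s",
                    paste(unique(markers$id[duplicated(markers$id)]), collapse = ", "))
  if (any(markers$pos < 1L, na.rm = TRUE))
    stop_validation("marker positions must be >= 1 (1-based coordinates)")
  if (any(markers$ref == markers$alt))
    stop_validation("REF and ALT alleles must differ")
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop_validation("genotype codes must be 0 (ref hom), 1 (alt hom) or NA")
  # canonical marker order: chromosome in order of first appearance, then position
  ord <- order(match(markers$chrom, unique(markers$chrom)), markers$pos)
  geno <- geno[, ord, drop = FALSE]
  markers <- markers[ord, , drop = FALSE]
  rownames(markers) <- NULL
  dimnames(geno) <- list(samples, markers$id)
  structure(list(geno = geno, samples = samples, markers = markers, note = note),
            class = "geno_matrix")
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d markers (%.1f%% missing)\n",
              nrow(x$geno), ncol(x$geno), 100 * mean(is.na(x$geno))))
  if (nzchar(x$note)) cat(" note:", x$note, "\n")
  invisible(x)
}

#' @export
`==.geno_matrix` <- function(e1, e2) {
  identical(e1$samples, e2$samples) &&
    identical(e1$markers[c("id", "chrom", "pos", "ref", "alt")],
              e2$markers[c("id", "chrom", "pos", "ref", "alt")]) &&
    identical(unname(e1$geno), unname(e2$geno))
}

is_imputed_matrix <- function(x) inherits(x, "geno_imputed")

#' Extract the genotype code grid
#'
#' @param x a `geno_matrix` or `geno_imputed` object.
#' @return Integer matrix of genotype codes (samples x markers).
#' @export
geno_codes <- function(x) {
  if (is_imputed_matrix(x)) x$base$geno else x$geno
}

marker_table <- function(x) {
  if (is_imputed_matrix(x)) x$base$markers else x$markers
}

sample_labels <- function(x) {
  if (is_imputed_matrix(x)) x$base$samples else x$samples
}
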