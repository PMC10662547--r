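#' Read a VCF into a genotype matrix
#'
#' Reads a plain or gzip-compressed VCF and encodes diploid genotypes as
#' three-valued codes: `0/0` becomes 0 (reference homozygote), `1/1`
#' becomes 1 (alternate homozygote), `./.` becomes `NA`. Heterozygous
#' calls (`0/1`, `1/0`) are masked to `NA` by default, reflecting the
#' preprocessing convention that heterozygous sites are treated as missing
#' data in inbred germplasm panels. Phased separators (`|`) are accepted
#' and treated like `/`. Only biallelic SNP records are kept; multiallelic
#' records and indels are skipped and the skip count is reported via a
#' message and the `"skipped"` attribute.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file.
#' @param het_as_missing mask heterozygous calls as missing (default
#'   `TRUE`). The genotype model has no heterozygote state, so `FALSE`
#'   raises an error if heterozygous calls are present.
#' @return A [geno_matrix()] with markers sorted by chromosome and
#'   position; attribute `"skipped"` holds the number of non-biallelic-SNP
#'   records dropped.
#' @export
read_vcf <- function(path, het_as_missing = TRUE) {
  if (!file.exists(path)) stop_io("cannot read VCF: no such file '%s'", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop_io("failed to parse VCF '%s': %s",
                                            path, conditionMessage(e)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  if (n_rec == 0L) stop_validation("VCF '%s' contains no variant records", path)
  nuc <- c("A", "C", "G", "T", "a", "c", "g", "t")
  keep <- !is.na(fix$REF) & !is.na(fix$ALT) &
    fix$REF %in% nuc & fix$ALT %in% nuc
  skipped <- sum(!keep)
  if (!any(keep))
    stop_validation("VCF '%s' contains no biallelic SNP records", path)
  if (skipped > 0L)
    message(sprintf("read_vcf: skipped %d non-biallelic-SNP record(s)", skipped))

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  samples <- colnames(gt)
  if (anyDuplicated(samples))
    stop_validation("duplicate sample labels in VCF '%s'", path)

  gsub_sep <- gsub("|", "/", as.vector(gt), fixed = TRUE)
  code <- rep(NA_integer_, length(gsub_sep))
  code[gsub_sep %in% "0/0"] <- 0L
  code[gsub_sep %in% "1/1"] <- 1L
  het <- gsub_sep %in% c("0/1", "1/0")
  if (any(het) && !het_as_missing)
    stop_validation("heterozygous calls present and het_as_missing = FALSE; the genotype model has no heterozygote state")
  # everything else (./., .|., NA, hets) stays NA
  geno <- matrix(code, nrow = nrow(gt), ncol = ncol(gt))  # markers x samples
  ids <- fix$ID
  miss_id <- is.na(ids) | ids == "."
  ids[miss_id] <- paste0(fix$CHROM[miss_id], "_", fix$POS[miss_id])
  markers <- data.frame(id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                        ref = toupper(fix$REF), alt = toupper(fix$ALT),
                        stringsAsFactors = FALSE)
  gm <- geno_matrix(t(geno), markers, samples = samples,
                    note = sprintf("read from %s", basename(path)))
  attr(gm, "skipped") <- skipped
  gm
}

#' Write a genotype matrix as minimal VCF 4.2
#'
#' Emits an uncompressed VCF with the standard eight fixed columns
#' (QUAL/FILTER/INFO set to `.`) and a GT-only FORMAT. Codes are written
#' as `0/0`, `1/1` and `./.`.
#'
#' @param matrix a [geno_matrix()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(matrix, path) {
  stopifnot(inherits(matrix, "geno_matrix"))
  gt_strings <- matrix(c("0/0", "1/1")[matrix$geno + 1L],
                       nrow = nrow(matrix$geno))
  gt_strings[is.na(matrix$geno)] <- "./."
  write_vcf_strings(gt_strings, matrix$markers, matrix$samples, path)
}

# shared emitter: gt samples x markers character matrix of GT strings
write_vcf_strings <- function(gt, markers, samples, path) {
  header <- c("##fileformat=VCFv4.2",
              "##source=snpcore",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(markers$chrom, markers$pos, markers$id, markers$ref,
                markers$alt, ".", ".", ".", "GT",
                apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_io("cannot write VCF to '%s'", path))
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Filter samples and markers by missing-data rate
#'
#' Removes samples whose genotype missing rate is at or above
#' `sample_max`, then removes markers whose missing rate — recomputed on
#' the retained samples — is at or above `marker_max`. The defaults (0.5
#' for samples, 0.2 for markers) are the conventional thresholds for
#' array/GBS germplasm panels. Order of retained samples and markers is
#' preserved.
#'
#' @param matrix a [geno_matrix()].
#' @param sample_max,marker_max removal thresholds in `[0, 1]`; a unit
#'   with missing rate `>= ` its threshold is removed.
#' @return A list with elements `matrix` (the filtered [geno_matrix()])
#'   and `report` (a `filter_report` listing removals and their rates).
#' @export
filter_by_missingness <- function(matrix, sample_max = 0.5, marker_max = 0.2) {
  stopifnot(inherits(matrix, "geno_matrix"))
  if (sample_max < 0 || sample_max > 1 || marker_max < 0 || marker_max > 1)
    stop_validation("missing-rate thresholds must lie in [0, 1]")
  miss <- is.na(matrix$geno)
  s_rate <- rowMeans(miss)
  s_drop <- s_rate >= sample_max
  if (all(s_drop))
    stop_validation("all samples removed at sample threshold %.3g; raise the threshold", sample_max)
  miss2 <- miss[!s_drop, , drop = FALSE]
  m_rate <- colMeans(miss2)
  m_drop <- m_rate >= marker_max
  if (all(m_drop))
    stop_validation("all markers removed at marker threshold %.3g; raise the threshold", marker_max)
  out <- geno_matrix(matrix$geno[!s_drop, !m_drop, drop = FALSE],
                     matrix$markers[!m_drop, , drop = FALSE],
                     samples = matrix$samples[!s_drop],
                     note = matrix$note)
  report <- structure(list(
    samples_removed = data.frame(sample = matrix$samples[s_drop],
                                 missing_rate = unname(s_rate[s_drop]),
                                 stringsAsFactors = FALSE),
    markers_removed = data.frame(marker = matrix$markers$id[m_drop],
                                 missing_rate = unname(m_rate[m_drop]),
                                 stringsAsFactors = FALSE),
    thresholds = c(sample_max = sample_max, marker_max = marker_max)),
    class = "filter_report")
  list(matrix = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: removed %d sample(s) (rate >= %.3g), %d marker(s) (rate >= %.3g)\n",
              nrow(x$samples_removed), x$thresholds[["sample_max"]],
              nrow(x$markers_removed), x$thresholds[["marker_max"]]))
  invisible(x)
}

#' Impute missing calls with the major homozygote
#'
#' Fills every missing cell with that marker's most frequent genotype
#' among the non-missing calls. A tie between reference and alternate
#' homozygote counts is broken toward the reference homozygote
#' (deterministic and reference-stable). The positions of imputed cells
#' are recorded so downstream pair resolution can be audited on observed
#' data only.
#'
#' @param matrix a [geno_matrix()]; every marker must have at least one
#'   non-missing call.
#' @return A `geno_imputed` object: list with `base` (a [geno_matrix()]
#'   with no missing cells) and `imputed_mask` (logical matrix, `TRUE`
#'   where a cell was filled).
#' @export
impute_major <- function(matrix) {
  stopifnot(inherits(matrix, "geno_matrix"))
  g <- matrix$geno
  mask <- is.na(g)
  n_alt <- colSums(g == 1L, na.rm = TRUE)
  n_obs <- colSums(!mask)
  if (any(n_obs == 0L))
    stop_validation("marker(s) with all calls missing (filter first): %s",
                    paste(matrix$markers$id[n_obs == 0L], collapse = ", "))
  major <- ifelse(n_alt > n_obs - n_alt, 1L, 0L)  # tie -> REF_HOM
  fill <- which(mask, arr.ind = TRUE)
  g[fill] <- major[fill[, 2L]]
  base <- geno_matrix(g, matrix$markers, samples = matrix$samples,
                      note = matrix$note)
  structure(list(base = base, imputed_mask = mask), class = "geno_imputed")
}

#' @export
print.geno_imputed <- function(x, ...) {
  cat(sprintf("geno_imputed: %d samples x %d markers, %d cell(s) imputed with the major homozygote\n",
              nrow(x$base$geno), ncol(x$base$geno), sum(x$imputed_mask)))
  invisible(x)
}

#' Read a marker id list
#'
#' One marker id per line; blank lines and `#` comments are ignored.
#'
#' @param path text file path.
#' @return Character vector of marker ids.
#' @export
read_marker_list <- function(path) {
  if (!file.exists(path)) stop_io("cannot read marker list: no such file '%s'", path)
  x <- readLines(path, warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x[nzchar(x)]
}
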