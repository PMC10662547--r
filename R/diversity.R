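#' Shannon diversity index
#'
#' Computes `H = -sum(P_i * ln(P_i))` over a frequency vector (natural
#' log). Zero frequencies contribute nothing, so `H` is invariant to
#' padding with empty categories. In panel selection the frequencies are
#' those of the multilocus genotype labels ("haplotypes") formed over the
#' currently selected markers, and `H` is the greedy objective.
#'
#' @param freqs numeric vector of proportions summing to 1.
#' @param tol tolerance on `sum(freqs) == 1`.
#' @return Non-negative scalar.
#' @export
shannon_index <- function(freqs, tol = 1e-8) {
  if (any(freqs < 0 | freqs > 1))
    stop_validation("frequencies must lie in [0, 1]")
  if (abs(sum(freqs) - 1) > tol)
    stop_validation("frequencies sum to %.10g, not 1", sum(freqs))
  p <- freqs[freqs > 0]
  -sum(p * log(p))
}

#' Polymorphism information content, simplified form
#'
#' For a biallelic locus with allele frequencies `(p, 1 - p)` the
#' simplified PIC is the expected heterozygosity `1 - p^2 - (1 - p)^2`.
#'
#' @param p allele frequency (vectorised), in `[0, 1]`.
#' @return PIC value(s) in `[0, 0.5]`.
#' @export
pic_simple <- function(p) {
  if (any(p < 0 | p > 1)) stop_validation("allele frequency outside [0, 1]")
  1 - p^2 - (1 - p)^2
}

#' Polymorphism information content, full form
#'
#' The full PIC subtracts the pairwise term from the simplified form:
#' `1 - sum(P_i^2) - sum_{i<j} 2 P_i^2 P_j^2`, which for a biallelic
#' locus with frequencies `(p, q = 1 - p)` is `1 - p^2 - q^2 - 2 p^2 q^2`.
#' Its maximum over `p` is 0.375, attained at `p = 0.5`.
#'
#' @inheritParams pic_simple
#' @return PIC value(s) in `[0, 0.375]`.
#' @export
pic_full <- function(p) {
  if (any(p < 0 | p > 1)) stop_validation("allele frequency outside [0, 1]")
  q <- 1 - p
  1 - p^2 - q^2 - 2 * p^2 * q^2
}

#' Per-marker diversity summaries
#'
#' For each marker: minor allele frequency (computed on observed calls;
#' with heterozygotes masked the allele frequency equals the homozygote
#' genotype frequency), missing rate, both PIC forms at the marker's
#' allele frequency, and the Shannon index over the marker's observed
#' genotype frequencies. Monomorphic markers get MAF 0 and PIC 0.
#'
#' @param matrix a [geno_matrix()] or `geno_imputed` object.
#' @return data.frame with columns `marker_id`, `maf`, `missing_rate`,
#'   `pic_simple`, `pic_full`, `shannon`.
#' @export
marker_summaries <- function(matrix) {
  g <- geno_codes(matrix)
  mk <- marker_table(matrix)
  n_obs <- colSums(!is.na(g))
  n_alt <- colSums(g == 1L, na.rm = TRUE)
  p_alt <- ifelse(n_obs > 0, n_alt / n_obs, NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  shan <- vapply(seq_len(ncol(g)), function(j) {
    obs <- g[, j][!is.na(g[, j])]
    if (!length(obs)) return(NA_real_)
    shannon_index(tabulate(obs + 1L, nbins = 2L) / length(obs))
  }, numeric(1))
  data.frame(marker_id = mk$id,
             maf = maf,
             missing_rate = colMeans(is.na(g)),
             pic_simple = pic_simple(p_alt),
             pic_full = pic_full(p_alt),
             shannon = shan,
             stringsAsFactors = FALSE)
}

#' Pairwise identity-by-state matrix
#'
#' `IBS(a, b)` is the proportion of markers, among those observed
#' (non-missing) in both samples, at which the two genotype codes agree.
#' Pairs with no jointly observed marker are `NaN` and their indices are
#' returned in the `"undefined_pairs"` attribute. The diagonal is 1.
#'
#' @param matrix a [geno_matrix()] or `geno_imputed` object with at least
#'   two samples.
#' @return Symmetric numeric matrix with sample labels as dimnames.
#' @export
ibs_matrix <- function(matrix) {
  g <- geno_codes(matrix)
  if (nrow(g) < 2L) stop_validation("IBS requires at least two samples")
  obs <- !is.na(g)
  is0 <- obs & g == 0L
  is1 <- obs & g == 1L
  is0[!obs] <- FALSE; is1[!obs] <- FALSE
  match_cnt <- tcrossprod(is0 * 1) + tcrossprod(is1 * 1)
  joint <- tcrossprod(obs * 1)
  ibs <- match_cnt / joint   # NaN where joint == 0
  diag(ibs) <- 1
  dimnames(ibs) <- list(sample_labels(matrix), sample_labels(matrix))
  undef <- which(joint == 0 & upper.tri(joint), arr.ind = TRUE)
  attr(ibs, "undefined_pairs") <- undef
  ibs
}

#' Pairwise linkage-disequilibrium r-squared
#'
#' Squared Pearson correlation of the 0/1 genotype codes of two markers
#' across samples. With heterozygotes masked this is a genotype-based
#' (not haplotype-phase) r-squared. Symmetric in its arguments and
#' invariant to swapping either marker's allele coding.
#'
#' @param matrix a `geno_imputed` (or complete [geno_matrix()]).
#' @param marker_a,marker_b marker ids.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(matrix, marker_a, marker_b) {
  g <- geno_codes(matrix)
  mk <- marker_table(matrix)
  ia <- match(marker_a, mk$id); ib <- match(marker_b, mk$id)
  if (is.na(ia) || is.na(ib))
    stop_validation("unknown marker id(s): %s",
                    paste(c(marker_a, marker_b)[is.na(c(ia, ib))], collapse = ", "))
  a <- g[, ia]; b <- g[, ib]
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(unique(a)) < 2L || length(unique(b)) < 2L)
    stop_validation("LD r2 undefined: monomorphic marker among '%s', '%s'",
                    marker_a, marker_b)
  cor(a, b)^2
}

#' Export a pairwise matrix or marker summary table as TSV
#'
#' @param x a matrix or data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  if (is.matrix(x)) x <- data.frame(label = rownames(x), x, check.names = FALSE)
  tryCatch(write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE),
           error = function(e) stop_io("cannot write '%s'", path))
  invisible(path)
}
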