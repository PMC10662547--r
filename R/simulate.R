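#' Simulation specification
#'
#' Describes a synthetic diploid inbred genotype panel: a MAF spectrum,
#' linkage-disequilibrium blocks of correlated markers, per-cell missing
#' and heterozygote rates, and optional planted duplicate or
#' near-duplicate samples. The defaults sketch a mid-sized germplasm
#' panel genotyped on an array: 200 samples, 2,000 markers on 7
#' chromosomes, MAF uniform on (0.05, 0.5), 5% missing calls, 2%
#' residual heterozygotes, LD blocks of 10 markers at correlation 0.8.
#'
#' @param n_samples,n_markers,n_chromosomes panel dimensions.
#' @param maf either `c(low, high)` for a uniform MAF spectrum or
#'   `list(beta = c(shape1, shape2))` for a Beta spectrum (rescaled to
#'   `[0, 0.5]`).
#' @param missing_rate,het_rate per-cell rates; heterozygotes exist only
#'   to exercise het-to-missing masking.
#' @param ld_block_size markers per correlated block.
#' @param ld_block_rho target correlation between a block's founder
#'   column and its copies, in `[0, 1]`.
#' @param n_duplicates exact-duplicate sample pairs to plant.
#' @param n_near_duplicates near-duplicate pairs differing at exactly
#'   `near_dup_d` markers.
#' @param near_dup_d differing-marker count for near-duplicates.
#' @param seed RNG seed.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_samples = 200L, n_markers = 2000L, n_chromosomes = 7L,
                     maf = c(0.05, 0.5), missing_rate = 0.05, het_rate = 0.02,
                     ld_block_size = 10L, ld_block_rho = 0.8,
                     n_duplicates = 0L, n_near_duplicates = 0L,
                     near_dup_d = 1L, seed = 1L) {
  rates <- c(missing_rate, het_rate)
  if (any(rates < 0 | rates > 1))
    stop_validation("rates must lie in [0, 1]")
  if (ld_block_rho < 0 || ld_block_rho > 1)
    stop_validation("ld_block_rho must lie in [0, 1]")
  if (n_duplicates + n_near_duplicates > n_samples / 2)
    stop_validation("too many planted pairs for %d samples", n_samples)
  structure(list(n_samples = as.integer(n_samples),
                 n_markers = as.integer(n_markers),
                 n_chromosomes = as.integer(n_chromosomes),
                 maf = maf, missing_rate = missing_rate, het_rate = het_rate,
                 ld_block_size = as.integer(ld_block_size),
                 ld_block_rho = ld_block_rho,
                 n_duplicates = as.integer(n_duplicates),
                 n_near_duplicates = as.integer(n_near_duplicates),
                 near_dup_d = as.integer(near_dup_d),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

draw_maf <- function(spec, n) {
  if (is.list(spec$maf) && !is.null(spec$maf$beta))
    0.5 * stats::rbeta(n, spec$maf$beta[1], spec$maf$beta[2])
  else
    runif(n, spec$maf[1], spec$maf[2])
}

#' Simulate a genotype panel with known ground truth
#'
#' Markers are laid out block by block along chromosomes (positions are
#' cumulative jumps of 1-10 kb). Each LD block draws one founder column
#' with alternate-homozygote frequency from the MAF spectrum; the other
#' columns of the block copy the founder with probability `ld_block_rho`
#' and are redrawn at the same frequency otherwise, so the
#' founder-to-copy genotype correlation equals `ld_block_rho` in
#' expectation. Duplicate and near-duplicate sample pairs are planted by
#' row copying (plus exactly `near_dup_d` genotype flips); the flipped
#' cells are protected from the missing/heterozygote sprinkle so the
#' planted differences stay observable. Finally missing (`./.`) and
#' heterozygous (`0/1`) calls are sprinkled at the stated per-cell rates;
#' heterozygotes are masked to missing in the returned matrix, exactly as
#' VCF ingest would do.
#'
#' @param spec a [sim_spec()].
#' @return List of class `sim_result`: `geno` (a [geno_matrix()] with
#'   masked cells as `NA`), `gt` (character matrix of VCF GT strings
#'   including the raw `0/1` calls), and `manifest` (ground truth:
#'   planted pairs, block map, true per-marker MAF, realized missing and
#'   het cell counts, feasibility warning if full discrimination is
#'   impossible).
#' @export
simulate_genotypes <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- spec$n_samples; p <- spec$n_markers
  withr::with_seed(spec$seed, {
    per_chrom <- diff(round(seq(0, p, length.out = spec$n_chromosomes + 1)))
    chrom <- rep(paste0("chr", seq_len(spec$n_chromosomes)), per_chrom)
    pos <- unlist(lapply(per_chrom, function(k)
      cumsum(sample(1000:10000, k, replace = TRUE))), use.names = FALSE)

    # block ids never straddle a chromosome boundary
    block <- integer(p); boff <- 0L; start <- 1L
    for (k in per_chrom) {
      if (k == 0L) next
      idx <- start:(start + k - 1L)
      block[idx] <- boff +
        rep(seq_len(ceiling(k / spec$ld_block_size)),
            each = spec$ld_block_size)[seq_len(k)]
      boff <- max(block[idx]); start <- start + k
    }
    # founder frequency per block, shared by the whole block
    maf_block <- draw_maf(spec, max(block))
    true_maf <- maf_block[block]

    g <- matrix(0L, n, p)
    for (b in seq_len(max(block))) {
      cols <- which(block == b)
      q <- maf_block[b]
      founder <- rbinom(n, 1L, q)
      g[, cols[1]] <- founder
      for (j in cols[-1]) {
        copy <- runif(n) < spec$ld_block_rho
        g[, j] <- ifelse(copy, founder, rbinom(n, 1L, q))
      }
    }

    # plant duplicates at the tail: pair k copies row k
    dup_pairs <- near_pairs <- NULL
    protected <- matrix(FALSE, n, p)
    if (spec$n_duplicates > 0) {
      dup_pairs <- cbind(a = seq_len(spec$n_duplicates),
                         b = n - seq_len(spec$n_duplicates) + 1L)
      for (k in seq_len(spec$n_duplicates)) g[dup_pairs[k, 2], ] <- g[dup_pairs[k, 1], ]
    }
    if (spec$n_near_duplicates > 0) {
      src <- spec$n_duplicates + seq_len(spec$n_near_duplicates)
      dst <- n - spec$n_duplicates - seq_len(spec$n_near_duplicates) + 1L
      near_pairs <- cbind(a = src, b = dst, d = spec$near_dup_d)
      for (k in seq_len(spec$n_near_duplicates)) {
        g[dst[k], ] <- g[src[k], ]
        flip <- sample.int(p, spec$near_dup_d)
        g[dst[k], flip] <- 1L - g[dst[k], flip]
        protected[dst[k], flip] <- TRUE
        protected[src[k], flip] <- TRUE
      }
    }

    # sprinkle heterozygote and missing calls on unprotected cells
    u <- matrix(runif(n * p), n, p)
    het_cells <- u < spec$het_rate & !protected
    miss_cells <- u >= spec$het_rate &
      u < spec$het_rate + spec$missing_rate & !protected

    gt <- matrix(c("0/0", "1/1")[g + 1L], n, p)
    gt[het_cells] <- "0/1"
    gt[miss_cells] <- "./."
    g[het_cells | miss_cells] <- NA_integer_

    markers <- data.frame(id = sprintf("M%05d", seq_len(p)),
                          chrom = chrom, pos = pos,
                          ref = "A", alt = "G", stringsAsFactors = FALSE)
    samples <- sprintf("S%04d", seq_len(n))
    gm <- geno_matrix(g, markers, samples = samples, note = "simulated")

    n_free <- n - spec$n_duplicates
    manifest <- list(
      spec = unclass(spec),
      duplicate_pairs = if (is.null(dup_pairs)) NULL else
        data.frame(sample_a = samples[dup_pairs[, 1]],
                   sample_b = samples[dup_pairs[, 2]], stringsAsFactors = FALSE),
      near_duplicate_pairs = if (is.null(near_pairs)) NULL else
        data.frame(sample_a = samples[near_pairs[, 1]],
                   sample_b = samples[near_pairs[, 2]],
                   d = near_pairs[, 3], stringsAsFactors = FALSE),
      block_map = data.frame(marker_id = markers$id, block = block,
                             stringsAsFactors = FALSE),
      true_maf = setNames(pmin(true_maf, 1 - true_maf), markers$id),
      n_het_cells = sum(het_cells),
      n_missing_cells = sum(miss_cells),
      feasibility_warning = if (2^p < n_free)
        "full discrimination impossible: fewer label combinations than samples"
      else NULL)

    structure(list(geno = gm, gt = gt, manifest = manifest),
              class = "sim_result")
  })
}

#' Write a simulated panel as VCF, preserving raw heterozygous calls
#'
#' Unlike [write_vcf()] on the masked matrix, this writes the original
#' `0/1` calls so that re-reading the file exercises the
#' heterozygote-masking path.
#'
#' @param sim a `sim_result` from [simulate_genotypes()].
#' @param path output VCF path.
#' @return Invisibly, `path`.
#' @export
write_sim_vcf <- function(sim, path) {
  stopifnot(inherits(sim, "sim_result"))
  write_vcf_strings(sim$gt, sim$geno$markers, sim$geno$samples, path)
}

#' Deterministic 8-sample x 8-marker toy panel
#'
#' A hand-built fixture exercising every selection rule at once: three
#' balanced markers jointly encode all eight samples (so the exhaustive
#' minimum panel size is 3), a fourth marker duplicates the first (fully
#' linked, 1 kb apart), one marker is monomorphic, the remaining three
#' are unbalanced distractors and one of them carries a missing call.
#' All sample pairs are distinguishable on observed genotypes.
#'
#' @return A [geno_matrix()].
#' @export
toy_fixture <- function() {
  g <- rbind(
    #        M1 M4 M5 M2 M3 M6 M7 M8   (pre-sort layout, see markers below)
    S1 = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
    S2 = c(0L, 0L, 0L, 0L, 1L, 0L, 1L, 0L),
    S3 = c(0L, 0L, 0L, 1L, 0L, 0L, 1L, 0L),
    S4 = c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 0L),
    S5 = c(1L, 1L, 0L, 0L, 0L, 0L, 1L, 0L),
    S6 = c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 1L),
    S7 = c(1L, 1L, 0L, 1L, 0L, 0L, 1L, 1L),
    S8 = c(1L, 1L, 0L, 1L, 1L, 1L, 1L, NA))
  markers <- data.frame(
    id = c("M1", "M4", "M5", "M2", "M3", "M6", "M7", "M8"),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2", "chr3", "chr3"),
    pos = c(1000L, 2000L, 500000L, 1000L, 90000L, 400000L, 1000L, 250000L),
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  geno_matrix(g, markers, samples = rownames(g), note = "toy fixture")
}
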