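#' Recompute the discrimination saturation curve of a core set
#'
#' Distinct multilocus genotype labels after each successive core marker,
#' on the imputed matrix. Serves as double-entry bookkeeping against the
#' counts recorded during selection.
#'
#' @param core a `core_set` or character vector of marker ids (order
#'   matters).
#' @param matrix a `geno_imputed` (or complete [geno_matrix()]).
#' @return List of class `saturation_curve`: `steps`, `distinct_counts`,
#'   `sample_total`.
#' @export
saturation <- function(core, matrix) {
  ids <- if (inherits(core, "core_set")) core$marker_ids else as.character(core)
  if (!length(ids)) stop_validation("core set is empty")
  g <- geno_codes(matrix)
  mk <- marker_table(matrix)
  sel <- match(ids, mk$id)
  if (anyNA(sel))
    stop_validation("marker(s) absent from matrix: %s",
                    paste(ids[is.na(sel)], collapse = ", "))
  gid <- rep(1L, nrow(g))
  counts <- integer(length(sel))
  for (i in seq_along(sel)) {
    key <- gid * 2L + g[, sel[i]]
    gid <- match(key, unique(key))
    counts[i] <- length(unique(gid))
  }
  structure(list(steps = seq_along(sel), distinct_counts = counts,
                 sample_total = nrow(g)),
            class = "saturation_curve")
}

#' @export
print.saturation_curve <- function(x, ...) {
  cat(sprintf("saturation_curve: %d steps, %d/%d samples distinguished\n",
              length(x$steps), x$distinct_counts[length(x$steps)],
              x$sample_total))
  invisible(x)
}

#' Random-selection baseline
#'
#' The naive alternative to greedy selection: draw `per_arm` markers with
#' MAF above `maf_min` from the long and the short arm of every
#' chromosome, and count the distinct haplotype labels the draw yields.
#' Arm boundaries default to each chromosome's midpoint (mean of its
#' lowest and highest marker position) and can be overridden with a
#' `chrom -> centromere position` table. An arm with fewer eligible
#' markers than `per_arm` contributes all its eligible markers (logged in
#' the result).
#'
#' @param matrix a `geno_imputed` (or complete [geno_matrix()]).
#' @param per_arm markers per chromosome arm (default 2).
#' @param maf_min MAF strictly-greater-than eligibility cutoff in
#'   `[0, 0.5)` (default 0.3).
#' @param draws number of independent draws (default 20).
#' @param seed RNG seed.
#' @param centromeres optional data.frame/list with `chrom` and `pos`.
#' @return List of class `random_baseline`: `counts` (distinct labels per
#'   draw), `sets` (marker ids per draw), `short_arms` (log of arms with
#'   a deficit).
#' @export
random_baseline <- function(matrix, per_arm = 2L, maf_min = 0.3,
                            draws = 20L, seed = 1L, centromeres = NULL) {
  g <- geno_codes(matrix)
  mk <- marker_table(matrix)
  if (maf_min < 0 || maf_min >= 0.5)
    stop_validation("maf_min must lie in [0, 0.5)")
  maf <- marker_summaries(matrix)$maf
  chroms <- unique(mk$chrom)
  cen <- setNames(vapply(chroms, function(ch) {
    pos <- mk$pos[mk$chrom == ch]
    (min(pos) + max(pos)) / 2
  }, numeric(1)), chroms)
  if (!is.null(centromeres)) {
    cen[as.character(centromeres$chrom)] <- as.numeric(centromeres$pos)
  }
  arm_of <- ifelse(mk$pos <= cen[mk$chrom], "S", "L")
  eligible <- maf > maf_min
  if (!any(eligible))
    warning("no markers pass the MAF cutoff; draws are empty")
  arms <- split(which(eligible), paste0(mk$chrom[eligible], ":", arm_of[eligible]))

  short_arms <- character(0)
  counts <- integer(draws)
  sets <- vector("list", draws)
  withr::with_seed(seed, {
    for (d in seq_len(draws)) {
      picked <- unlist(lapply(arms, function(idx) {
        if (length(idx) <= per_arm) idx else sample(idx, per_arm)
      }), use.names = FALSE)
      deficit <- names(arms)[vapply(arms, length, integer(1)) < per_arm]
      short_arms <- union(short_arms, deficit)
      sets[[d]] <- mk$id[sort(picked)]
      counts[d] <- if (length(picked))
        n_distinct_key(interaction_ids(g, sort(picked))) else 1L
    }
  })
  structure(list(counts = counts, sets = sets, per_arm = per_arm,
                 maf_min = maf_min, short_arms = short_arms),
            class = "random_baseline")
}

#' Genetic distance matrix (1 - IBS)
#'
#' @param matrix a [geno_matrix()] or `geno_imputed`.
#' @param marker_subset optional marker ids to restrict to (e.g. a core
#'   set); default all markers.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(matrix, marker_subset = NULL) {
  if (!is.null(marker_subset)) {
    ids <- if (inherits(marker_subset, "core_set"))
      marker_subset$marker_ids else as.character(marker_subset)
    mk <- marker_table(matrix)
    sel <- match(ids, mk$id)
    if (anyNA(sel))
      stop_validation("marker(s) absent from matrix: %s",
                      paste(ids[is.na(sel)], collapse = ", "))
    if (is_imputed_matrix(matrix)) {
      matrix <- structure(list(
        base = geno_matrix(matrix$base$geno[, sel, drop = FALSE],
                           mk[sel, , drop = FALSE],
                           samples = matrix$base$samples),
        imputed_mask = matrix$imputed_mask[, sel, drop = FALSE]),
        class = "geno_imputed")
    } else {
      matrix <- geno_matrix(matrix$geno[, sel, drop = FALSE],
                            mk[sel, , drop = FALSE],
                            samples = matrix$samples)
    }
  }
  d <- 1 - ibs_matrix(matrix)
  diag(d) <- 0
  d
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation `r` of the vectorised upper triangles, with a
#' one-sided permutation p-value: rows and columns of the second matrix
#' are permuted jointly and `p = (1 + #\{r_perm >= r_obs\}) / (1 +
#' permutations)`.
#'
#' @param d1,d2 symmetric matrices with identical sample labels in
#'   identical order.
#' @param permutations number of permutations (>= 99).
#' @param seed RNG seed.
#' @return List of class `mantel_result`: `r`, `p_value`, `permutations`,
#'   `seed`.
#' @export
mantel_test <- function(d1, d2, permutations = 999L, seed = 1L) {
  if (!is.matrix(d1) || !is.matrix(d2) || !all(dim(d1) == dim(d2)))
    stop_validation("d1 and d2 must be matrices of identical dimension")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2)))
    stop_validation("sample labels of d1 and d2 differ")
  if (permutations < 99L) stop_validation("use at least 99 permutations")
  n <- nrow(d1)
  ut <- upper.tri(d1)
  v1 <- d1[ut]; v2 <- d2[ut]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop_validation("Mantel r undefined: a distance matrix has zero variance")
  r_obs <- cor(v1, v2)
  hits <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(permutations)) {
      perm <- sample.int(n)
      r_b <- cor(v1, d2[perm, perm][ut])
      if (r_b >= r_obs) hits <- hits + 1L
    }
  })
  structure(list(r = r_obs, p_value = (1 + hits) / (1 + permutations),
                 permutations = as.integer(permutations),
                 seed = as.integer(seed)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations)\n",
              x$r, x$p_value, x$permutations))
  invisible(x)
}
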