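#' Select a core SNP marker panel
#'
#' The main fitting function: from a genotype matrix, selects a minimal
#' set of markers whose combined genotypes distinguish every pair of
#' samples, with a guaranteed minimum of `m` observed (non-imputed)
#' marker differences per pair. Runs major-homozygote imputation, the
#' greedy Shannon-maximising primary pass and the missing-data recovery
#' pass, repeated `c` times under consecutive seeds, and returns the
#' smallest final panel.
#'
#' @param geno a [geno_matrix()], e.g. from [read_vcf()] after
#'   [filter_by_missingness()].
#' @param ... passed to [selection_config()] (`x`, `c`, `m`,
#'   `include_ids`, `exclude_ids`, `ld_prune_r2`, `ld_prune_window_bp`,
#'   `seed`).
#' @return The best `core_set`; all repetitions are attached as
#'   attribute `"runs"`.
#' @seealso [run_pipeline()] for the raw multi-run object,
#'   [verify_core()] to audit a panel.
#' @examples
#' gm <- toy_fixture()
#' core <- select_core(gm, seed = 1)
#' core
#' summary(core)
#' @export
select_core <- function(geno, ...) {
  run <- run_pipeline(geno, selection_config(...))
  best <- run$best
  attr(best, "runs") <- run$runs
  best
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core_set: %d marker(s) (%d primary + %d recovery)\n",
              length(x$marker_ids), x$primary_size, length(x$recovery_ids)))
  cat(sprintf(" samples: %d, distinct haplotype labels: %d\n",
              x$n_samples, x$distinct_final))
  nu <- if (is.null(x$unresolved_pairs)) 0L else nrow(x$unresolved_pairs)
  cat(sprintf(" unresolved pairs (insufficient observed differences): %d\n", nu))
  cat(" markers:", paste(head(x$marker_ids, 10), collapse = ", "),
      if (length(x$marker_ids) > 10) "...", "\n")
  invisible(x)
}

#' @export
summary.core_set <- function(object, ...) {
  df <- as.data.frame(object)
  structure(list(core = object, table = df), class = "summary.core_set")
}

#' @export
print.summary.core_set <- function(x, ...) {
  print(x$core)
  cat("\nPer-step detail:\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$core$unresolved_pairs) && nrow(x$core$unresolved_pairs)) {
    cat("\nUnresolved pairs:\n")
    print(x$core$unresolved_pairs[c("sample_a", "sample_b", "observed_diff")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Core set as a per-step marker table
#'
#' One row per selected marker, in selection order, with the distinct
#' haplotype count and Shannon index after that step, the marker's MAF
#' and full PIC, and whether it entered during the primary or recovery
#' pass.
#'
#' @param x a `core_set`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame.
#' @export
as.data.frame.core_set <- function(x, row.names = NULL, optional = FALSE, ...) {
  k <- length(x$marker_ids)
  phase <- rep(c("primary", "recovery"),
               c(x$primary_size, k - x$primary_size))
  data.frame(step = seq_len(k),
             marker_id = x$marker_ids,
             chrom = x$markers$chrom,
             pos = x$markers$pos,
             ref = x$markers$ref,
             alt = x$markers$alt,
             distinct = x$saturation,
             shannon = x$shannon_at_step,
             phase = phase,
             stringsAsFactors = FALSE)
}

#' Plot the discrimination saturation curve of a core set
#'
#' Distinct haplotype-label count against the number of selected markers;
#' the dashed line marks the number of samples (the ceiling).
#'
#' @param x a `core_set`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.core_set <- function(x, ...) {
  k <- seq_along(x$saturation)
  graphics::plot(k, x$saturation, type = "s", xlab = "markers selected",
                 ylab = "distinct haplotype labels",
                 main = "Discrimination saturation", ...)
  graphics::abline(h = x$n_samples, lty = 2)
  if (x$primary_size < length(k))
    graphics::abline(v = x$primary_size + 0.5, lty = 3)
  invisible(x)
}

#' Per-sample molecular passport table
#'
#' The multilocus genotype string of every sample over the core markers,
#' with missing observed calls shown as `.` — the registry identifier a
#' genebank would print for each accession.
#'
#' @param matrix_raw the [geno_matrix()] the core was selected from.
#' @param core a `core_set` or character vector of marker ids.
#' @return data.frame with `sample`, `passport` (string of 0/1/.), and
#'   one column per core marker.
#' @export
passport_table <- function(matrix_raw, core) {
  ids <- if (inherits(core, "core_set")) core$marker_ids else as.character(core)
  sel <- match(ids, matrix_raw$markers$id)
  if (anyNA(sel))
    stop_validation("unknown core marker(s): %s",
                    paste(ids[is.na(sel)], collapse = ", "))
  g <- matrix_raw$geno[, sel, drop = FALSE]
  ch <- matrix(as.character(g), nrow = nrow(g))
  ch[is.na(ch)] <- "."
  out <- data.frame(sample = matrix_raw$samples,
                    passport = apply(ch, 1L, paste, collapse = ""),
                    stringsAsFactors = FALSE)
  colnames(ch) <- ids
  cbind(out, as.data.frame(ch, stringsAsFactors = FALSE))
}
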