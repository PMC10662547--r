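# Independent oracles and fixture builders, deliberately written as plain
# loops so they share no code path with the package internals they check.

# random genotype matrix with optional planted missingness; every marker is
# guaranteed at least one observed call
rand_gm <- function(n, p, miss = 0, seed = 1) {
  withr::with_seed(seed, {
    g <- matrix(sample(0:1, n * p, replace = TRUE), n, p)
    if (miss > 0) {
      drop <- matrix(runif(n * p) < miss, n, p)
      for (j in seq_len(p)) if (all(drop[, j])) drop[1, j] <- FALSE
      g[drop] <- NA_integer_
    }
    # markers 2 Mb apart on one chromosome: outside the default LD-prune
    # window, so random instances exercise selection without pruning
    geno_matrix(g,
                data.frame(id = paste0("m", seq_len(p)),
                           chrom = "chr1",
                           pos = 2000000L * seq_len(p),
                           ref = "A", alt = "G", stringsAsFactors = FALSE),
                samples = paste0("s", seq_len(n)))
  })
}

# smallest marker subset whose rows are as distinct as the full matrix
# (brute-force enumeration over all subsets by increasing size)
exhaustive_min_core <- function(g) {
  stopifnot(!anyNA(g))
  n_labels <- function(cols) {
    key <- apply(g[, cols, drop = FALSE], 1L, paste, collapse = "")
    length(unique(key))
  }
  target <- n_labels(seq_len(ncol(g)))
  for (k in seq_len(ncol(g))) {
    combos <- utils::combn(ncol(g), k)
    for (i in seq_len(ncol(combos)))
      if (n_labels(combos[, i]) == target)
        return(list(size = k, subset = combos[, i], target = target))
  }
}

# plain O(n^2 m) IBS recount
brute_ibs <- function(g) {
  n <- nrow(g)
  out <- matrix(NA_real_, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    ok <- !is.na(g[a, ]) & !is.na(g[b, ])
    out[a, b] <- if (any(ok)) mean(g[a, ok] == g[b, ok]) else NaN
  }
  diag(out) <- 1
  out
}

# observed pairwise differences of one sample pair over a marker subset
brute_pair_diff <- function(g, a, b, cols = seq_len(ncol(g))) {
  ga <- g[a, cols]; gb <- g[b, cols]
  sum(!is.na(ga) & !is.na(gb) & ga != gb)
}

# write a VCF body from explicit GT strings (markers in rows)
write_raw_vcf <- function(path, samples, records) {
  header <- c("##fileformat=VCFv4.2",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
}
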