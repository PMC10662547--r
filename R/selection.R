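#' Selection configuration
#'
#' Bundles every tunable of the core-set search.
#'
#' @param x candidate extensions recorded per round (default 1). With
#'   `x > 1` the top-`x` Shannon-ranked candidates of each round are
#'   reported as alternatives; the main path always follows the
#'   top-ranked one.
#' @param c independent repetitions of the whole pipeline (default 1);
#'   repetition `r` runs under seed `seed + r - 1` and the smallest final
#'   set is reported as best.
#' @param m minimum number of observed (non-imputed) marker differences
#'   required per sample pair (default 1; use 2 to guard against
#'   genotyping noise).
#' @param include_ids marker ids forced into the set (seeded first).
#' @param exclude_ids marker ids barred from selection.
#' @param ld_prune_r2 r-squared threshold above which a marker near an
#'   already-selected marker becomes ineligible (default 0.8).
#' @param ld_prune_window_bp window, in bp, for the "nearby linked"
#'   exclusion (default 1e6).
#' @param seed integer seed governing all randomness (tie-breaks,
#'   repetition seeds).
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(x = 1L, c = 1L, m = 1L,
                             include_ids = character(), exclude_ids = character(),
                             ld_prune_r2 = 0.8, ld_prune_window_bp = 1e6,
                             seed = 1L) {
  x <- as.integer(x); c <- as.integer(c); m <- as.integer(m)
  if (x < 1L || c < 1L || m < 1L)
    stop_validation("x, c and m must all be >= 1")
  if (ld_prune_r2 < 0 || ld_prune_r2 > 1)
    stop_validation("ld_prune_r2 must lie in [0, 1]")
  include_ids <- as.character(include_ids %||% character())
  exclude_ids <- as.character(exclude_ids %||% character())
  if (length(intersect(include_ids, exclude_ids)))
    stop_validation("include and exclude lists overlap: %s",
                    paste(intersect(include_ids, exclude_ids), collapse = ", "))
  structure(list(x = x, c = c, m = m,
                 include_ids = include_ids, exclude_ids = exclude_ids,
                 ld_prune_r2 = ld_prune_r2,
                 ld_prune_window_bp = as.numeric(ld_prune_window_bp),
                 seed = as.integer(seed)),
            class = "selection_config")
}

# mark markers linked to (and near) a newly selected column as ineligible
prune_linked <- function(eligible, g, mk, j, r2_thr, window_bp) {
  cand <- which(eligible & mk$chrom == mk$chrom[j] &
                  abs(mk$pos - mk$pos[j]) <= window_bp)
  cand <- setdiff(cand, j)
  if (!length(cand)) return(eligible)
  v <- g[, j]
  if (length(unique(v)) < 2L) return(eligible)
  for (k in cand) {
    w <- g[, k]
    if (length(unique(w)) < 2L) next
    if (cor(v, w)^2 >= r2_thr) eligible[k] <- FALSE
  }
  eligible
}

#' Greedy Shannon-maximising marker selection (primary pass)
#'
#' Accumulates markers one per round on the imputed (complete) genotype
#' matrix. Each round, candidates that do not increase the number of
#' distinct multilocus genotype labels are skipped without evaluating the
#' Shannon index; among the remaining candidates the one maximising the
#' Shannon index of the resulting label frequencies is selected, with
#' exact ties broken uniformly at random under the run's seed.
#' Monomorphic markers and markers within `ld_prune_window_bp` of an
#' already-selected marker at r-squared `>= ld_prune_r2` are ineligible.
#' Markers on the include list are seeded into the set first; excluded
#' markers are never considered. The pass terminates when no eligible
#' marker increases the distinct label count — even if some sample pairs
#' remain identical (duplicates cannot be separated by any marker).
#'
#' @param matrix a `geno_imputed` object from [impute_major()].
#' @param config a [selection_config()].
#' @return An object of class `core_set` (primary pass: no recovery
#'   markers yet). Components include `marker_ids`, `saturation` (distinct
#'   label count after each step), `shannon_at_step`, `alternatives`
#'   (per-round top-`x` candidates when `x > 1`), `primary_size`.
#' @export
greedy_select <- function(matrix, config = selection_config()) {
  stopifnot(is_imputed_matrix(matrix))
  g <- geno_codes(matrix)
  mk <- marker_table(matrix)
  n <- nrow(g); p <- ncol(g)
  if (n < 2L) stop_validation("selection requires at least two samples")

  unknown <- setdiff(c(config$include_ids, config$exclude_ids), mk$id)
  if (length(unknown))
    stop_validation("unknown marker id(s) in include/exclude lists: %s",
                    paste(unknown, collapse = ", "))

  eligible <- rep(TRUE, p)
  eligible[mk$id %in% config$exclude_ids] <- FALSE
  mono <- apply(g, 2L, function(col) length(unique(col)) < 2L)
  # degenerate data (no polymorphism at all) yields an empty core set;
  # an eligible set emptied purely by the exclude list is a config error
  if (any(eligible & !mono) == FALSE && any(!mono) && !length(config$include_ids))
    stop_validation("all polymorphic markers are excluded; nothing to select from")
  eligible <- eligible & !mono

  selected <- integer(0)
  sat <- integer(0)
  shan <- numeric(0)
  alternatives <- list()
  gid <- rep(1L, n)          # current haplotype-label group per sample
  k_now <- 1L

  take <- function(j) {
    key <- gid * 2L + g[, j]
    gid <<- match(key, unique(key))
    st <- group_stats(gid)
    k_now <<- st$k
    selected <<- c(selected, j)
    sat <<- c(sat, st$k)
    shan <<- c(shan, st$H)
    eligible[j] <<- FALSE
    eligible <<- prune_linked(eligible, g, mk, j, config$ld_prune_r2,
                              config$ld_prune_window_bp)
  }

  withr::with_seed(config$seed, {
    for (id in config$include_ids) take(match(id, mk$id))

    repeat {
      if (k_now >= n) break
      cand <- which(eligible)
      if (!length(cand)) break
      nd <- vapply(cand, function(j) n_distinct_key(gid * 2L + g[, j]),
                   integer(1))
      inc <- nd > k_now          # the haplotype-count skip rule
      if (!any(inc)) break
      cand <- cand[inc]
      H <- vapply(cand, function(j) group_stats(gid * 2L + g[, j])$H,
                  numeric(1))
      best <- which(H >= max(H) - 1e-12)
      pick <- if (length(best) > 1L) sample(best, 1L) else best
      if (config$x > 1L) {
        ord <- order(H, decreasing = TRUE)[seq_len(min(config$x, length(cand)))]
        alternatives[[length(selected) + 1L]] <-
          data.frame(marker_id = mk$id[cand[ord]], shannon = H[ord],
                     stringsAsFactors = FALSE)
      }
      take(cand[pick])
    }
  })

  new_core_set(matrix, selected, sat, shan, alternatives, config,
               primary_size = length(selected), recovery_ids = character())
}

new_core_set <- function(matrix, selected, sat, shan, alternatives, config,
                         primary_size, recovery_ids,
                         unresolved_pairs = NULL, ledger = NULL) {
  mk <- marker_table(matrix)
  structure(list(
    marker_ids = mk$id[selected],
    markers = mk[selected, , drop = FALSE],
    saturation = sat,
    shannon_at_step = shan,
    alternatives = alternatives,
    primary_size = primary_size,
    recovery_ids = recovery_ids,
    unresolved_pairs = unresolved_pairs,
    ledger = ledger,
    config_used = config,
    seed_used = config$seed,
    n_samples = nrow(geno_codes(matrix)),
    distinct_final = if (length(sat)) sat[length(sat)] else 1L),
    class = "core_set")
}

# Observed-genotype pair ledger over a marker subset.
# raw_g: samples x markers integer matrix WITH NAs; sel: column indices.
build_ledger <- function(raw_g, imp_g, imp_mask, sel) {
  n <- nrow(raw_g)
  pairs <- pair_index(n)
  obs_diff <- integer(nrow(pairs))
  imp_diff <- integer(nrow(pairs))
  for (j in sel) {
    a <- raw_g[pairs[, 1L], j]; b <- raw_g[pairs[, 2L], j]
    obs_diff <- obs_diff + as.integer(!is.na(a) & !is.na(b) & a != b)
    imp_diff <- imp_diff +
      as.integer(imp_g[pairs[, 1L], j] != imp_g[pairs[, 2L], j])
  }
  data.frame(a = pairs[, 1L], b = pairs[, 2L],
             observed_diff = obs_diff,
             imputed_only_diff = imp_diff > 0L & obs_diff == 0L)
}

# Max achievable observed differences genome-wide for the given pair rows.
genomewide_obs_diff <- function(raw_g, a, b) {
  ra <- raw_g[a, ]; rb <- raw_g[b, ]
  sum(!is.na(ra) & !is.na(rb) & ra != rb)
}

#' Missing-data recovery pass
#'
#' The primary pass selects on imputed genotypes, so two samples may look
#' distinct only because a missing call was filled in. This pass rebuilds
#' the pair ledger on observed genotypes and, for every pair not yet
#' separated by at least `m` observed marker differences, greedily adds
#' the marker that is observed and differing in the largest number of
#' currently unresolved pairs (ties broken by higher minor allele
#' frequency, then by genome order), until every resolvable pair is
#' resolved at level `m`. Pairs with fewer than `m` observed differences
#' anywhere in the input (identical observed genotypes, e.g. IBS = 1
#' duplicates) are reported in `unresolved_pairs`, never looped on.
#'
#' @param matrix_raw the pre-imputation [geno_matrix()] (heterozygotes
#'   already masked).
#' @param imputed the `geno_imputed` object the primary pass ran on.
#' @param primary the `core_set` from [greedy_select()].
#' @param config a [selection_config()]; `config$m` is the guarantee level.
#' @return The final `core_set`, with `recovery_ids`, `unresolved_pairs`
#'   and the observed-genotype pair `ledger` filled in; `saturation` is
#'   extended over the recovery markers.
#' @export
recover_missing <- function(matrix_raw, imputed, primary,
                            config = primary$config_used) {
  stopifnot(inherits(matrix_raw, "geno_matrix"), is_imputed_matrix(imputed),
            inherits(primary, "core_set"))
  raw_g <- matrix_raw$geno
  imp_g <- geno_codes(imputed)
  mk <- marker_table(imputed)
  m_level <- config$m
  sel <- match(primary$marker_ids, mk$id)
  barred <- mk$id %in% config$exclude_ids

  ledger <- build_ledger(raw_g, imp_g, imputed$imputed_mask, sel)
  todo <- which(ledger$observed_diff < m_level)

  # split unresolved pairs into resolvable (enough observed differences
  # exist somewhere) and impossible
  capacity <- vapply(todo, function(i)
    genomewide_obs_diff(raw_g, ledger$a[i], ledger$b[i]), integer(1))
  impossible <- todo[capacity < m_level]
  open <- todo[capacity >= m_level]

  maf <- marker_summaries(matrix_raw)$maf
  added <- integer(0)
  if (length(open)) {
    # candidate separating markers per open pair (observed in both, differing)
    sep <- lapply(open, function(i) {
      ra <- raw_g[ledger$a[i], ]; rb <- raw_g[ledger$b[i], ]
      setdiff(which(!is.na(ra) & !is.na(rb) & ra != rb),
              c(sel, which(barred)))
    })
    need <- m_level - ledger$observed_diff[open]
    while (any(need > 0L)) {
      live <- need > 0L
      cover <- tabulate(unlist(sep[live]), nbins = ncol(raw_g))
      top <- max(cover)
      if (top == 0L) break  # exclusions consumed a pair's capacity
      tied <- which(cover == top)
      j <- tied[order(-maf[tied], tied)][1L]
      added <- c(added, j)
      hit <- vapply(sep, function(s) j %in% s, logical(1))
      need[hit] <- need[hit] - 1L
      sep <- lapply(sep, setdiff, j)
    }
    if (any(need > 0L))
      impossible <- sort(c(impossible, open[need > 0L]))
  }

  sel_final <- c(sel, added)
  ledger <- build_ledger(raw_g, imp_g, imputed$imputed_mask, sel_final)
  unresolved <- ledger[impossible, c("a", "b", "observed_diff"), drop = FALSE]
  unresolved$sample_a <- matrix_raw$samples[unresolved$a]
  unresolved$sample_b <- matrix_raw$samples[unresolved$b]
  rownames(unresolved) <- NULL

  # extend the saturation curve over the recovery markers
  sat <- primary$saturation; shan <- primary$shannon_at_step
  gid <- interaction_ids(imp_g, sel)
  for (j in added) {
    key <- gid * 2L + imp_g[, j]
    gid <- match(key, unique(key))
    st <- group_stats(gid)
    sat <- c(sat, st$k); shan <- c(shan, st$H)
  }

  out <- new_core_set(imputed, sel_final, sat, shan, primary$alternatives,
                      config, primary_size = primary$primary_size,
                      recovery_ids = mk$id[added],
                      unresolved_pairs = unresolved, ledger = ledger)
  out
}

# integer group ids of samples over columns `sel` of complete matrix g
interaction_ids <- function(g, sel) {
  n <- nrow(g)
  gid <- rep(1L, n)
  for (j in sel) {
    key <- gid * 2L + g[, j]
    gid <- match(key, unique(key))
  }
  gid
}

#' Run the full selection pipeline
#'
#' Executes imputation, the greedy primary pass and the missing-data
#' recovery pass `config$c` times under seeds `seed, seed + 1, ...` and
#' returns the smallest final core set (ties: first found) together with
#' all repetitions.
#'
#' @param matrix_raw a [geno_matrix()] (heterozygotes masked, filtered).
#' @param config a [selection_config()].
#' @return A list of class `core_run` with elements `best` (a `core_set`)
#'   and `runs` (list of all `c` core sets).
#' @export
run_pipeline <- function(matrix_raw, config = selection_config()) {
  stopifnot(inherits(matrix_raw, "geno_matrix"))
  imputed <- impute_major(matrix_raw)
  runs <- vector("list", config$c)
  for (r in seq_len(config$c)) {
    cfg_r <- config
    cfg_r$seed <- config$seed + r - 1L
    primary <- greedy_select(imputed, cfg_r)
    runs[[r]] <- recover_missing(matrix_raw, imputed, primary, cfg_r)
  }
  sizes <- vapply(runs, function(cs) length(cs$marker_ids), integer(1))
  structure(list(best = runs[[which.min(sizes)]], runs = runs,
                 sizes = sizes, config = config),
            class = "core_run")
}

#' Audit a core set against observed genotypes
#'
#' Recomputes the pair ledger from scratch over the core's markers on the
#' observed (pre-imputation) genotypes and checks that every pair that
#' *can* be separated by at least `m` observed differences somewhere in
#' the input is separated by at least `m` core markers.
#'
#' @param matrix_raw the pre-imputation [geno_matrix()].
#' @param core a `core_set`, or a character vector of marker ids.
#' @param m guarantee level (defaults to the core's configured `m`, or 1).
#' @return List with `pass` (logical), `ledger` (all-pairs observed-diff
#'   table), `offending` (pairs that fail the guarantee but could meet
#'   it), and `exempt` (pairs that cannot meet it on any marker set).
#' @export
verify_core <- function(matrix_raw, core, m = NULL) {
  stopifnot(inherits(matrix_raw, "geno_matrix"))
  ids <- if (inherits(core, "core_set")) core$marker_ids else as.character(core)
  if (is.null(m))
    m <- if (inherits(core, "core_set")) core$config_used$m else 1L
  raw_g <- matrix_raw$geno
  mk <- matrix_raw$markers
  sel <- match(ids, mk$id)
  if (anyNA(sel))
    stop_validation("core contains marker(s) absent from the matrix: %s",
                    paste(ids[is.na(sel)], collapse = ", "))
  imp <- impute_major(matrix_raw)
  ledger <- build_ledger(raw_g, geno_codes(imp), imp$imputed_mask, sel)
  short <- which(ledger$observed_diff < m)
  capacity <- vapply(short, function(i)
    genomewide_obs_diff(raw_g, ledger$a[i], ledger$b[i]), integer(1))
  offending <- short[capacity >= m]
  exempt <- short[capacity < m]
  lab <- function(i) data.frame(sample_a = matrix_raw$samples[ledger$a[i]],
                                sample_b = matrix_raw$samples[ledger$b[i]],
                                observed_diff = ledger$observed_diff[i],
                                stringsAsFactors = FALSE)
  list(pass = length(offending) == 0L,
       ledger = ledger,
       offending = lab(offending),
       exempt = lab(exempt),
       m = m)
}
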