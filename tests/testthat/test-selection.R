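test_that("greedy picks the two balanced markers on the classic 4-sample case", {
  g <- cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L), c(0L, 0L, 0L, 1L))
  gm <- rand_gm(4, 3, seed = 1); gm$geno <- g
  imp <- impute_major(gm)
  for (s in 1:5) {
    core <- greedy_select(imp, selection_config(seed = s))
    expect_setequal(core$marker_ids, c("m1", "m2"))
    expect_equal(core$saturation, c(2L, 4L))
  }
  # exhaustive enumeration confirms 2 is the optimum
  expect_equal(exhaustive_min_core(g)$size, 2L)
})

test_that("identical samples yield an empty core with every pair unresolved", {
  gm <- rand_gm(4, 5, seed = 2)
  gm$geno <- matrix(rep(gm$geno[1, ], each = 4), 4, 5)
  run <- run_pipeline(gm)
  expect_equal(run$best$primary_size, 0L)
  expect_equal(length(run$best$marker_ids), 0L)
  expect_equal(nrow(run$best$unresolved_pairs), choose(4, 2))
})

test_that("eight all-distinct samples need >= 3 markers and greedy gets there", {
  bits <- function(i) c(i %/% 4 %% 2, i %/% 2 %% 2, i %% 2)
  g <- t(sapply(0:7, function(i) as.integer(c(bits(i),
                                              rev(bits(i)),
                                              i %% 2, i %/% 4))))
  gm <- rand_gm(8, 8, seed = 3); gm$geno <- g
  core <- greedy_select(impute_major(gm), selection_config(seed = 1))
  expect_equal(core$distinct_final, 8L)
  expect_gte(length(core$marker_ids), 3L)          # ceil(log2 8) lower bound
  expect_gte(length(core$marker_ids), exhaustive_min_core(g)$size)
})

test_that("toy fixture: greedy attains the exhaustive optimum under every rule", {
  gm <- toy_fixture()
  imp <- impute_major(gm)
  opt <- exhaustive_min_core(geno_codes(imp))
  for (s in c(1, 7, 23, 101)) {
    core <- greedy_select(imp, selection_config(seed = s))
    expect_equal(core$distinct_final, 8L)
    expect_equal(length(core$marker_ids), opt$size)
    expect_false("M5" %in% core$marker_ids)                    # monomorphic
    expect_false(all(c("M1", "M4") %in% core$marker_ids))      # linked twins
  }
})

test_that("include and exclude lists are honoured", {
  gm <- toy_fixture()
  imp <- impute_major(gm)
  core <- greedy_select(imp, selection_config(include_ids = "M7",
                                              exclude_ids = "M2", seed = 1))
  expect_equal(core$marker_ids[1], "M7")
  expect_false("M2" %in% core$marker_ids)
  expect_equal(core$distinct_final, 8L)
  expect_error(greedy_select(imp, selection_config(include_ids = "nope")),
               class = "snpcore_validation_error")
  expect_error(selection_config(include_ids = "M1", exclude_ids = "M1"),
               class = "snpcore_validation_error")
})

test_that("selection is byte-reproducible under a fixed seed", {
  gm <- rand_gm(30, 80, miss = 0.08, seed = 4)
  r1 <- run_pipeline(gm, selection_config(seed = 9, c = 2))
  r2 <- run_pipeline(gm, selection_config(seed = 9, c = 2))
  expect_identical(r1$best, r2$best)
  expect_identical(r1$sizes, r2$sizes)
})

test_that("saturation is non-decreasing and bounded by min(n, 2^k)", {
  gm <- rand_gm(25, 60, miss = 0.05, seed = 5)
  core <- run_pipeline(gm)$best
  sat <- core$saturation
  expect_true(all(diff(sat) >= 0))
  expect_true(all(sat <= pmin(25, 2^seq_along(sat))))
})

test_that("recovery flags imputed-only pairs and adds the unique rescuer", {
  # s1, s2 share the observed genotype everywhere except m5; m4 separates
  # them only through an imputed call
  g <- rbind(s1 = c(0L, 0L, 0L, 0L, 0L),
             s2 = c(0L, 0L, 0L, NA, 1L),
             s3 = c(0L, 0L, 1L, 1L, 0L),
             s4 = c(0L, 1L, 0L, 1L, 0L),
             s5 = c(0L, 1L, 1L, 1L, 0L),
             s6 = c(1L, 0L, 0L, 1L, 0L))
  gm <- rand_gm(6, 5, seed = 6); gm$geno <- g
  imp <- impute_major(gm)
  expect_equal(unname(geno_codes(imp)[2, 4]), 1L)   # major fill separates s1/s2
  primary <- greedy_select(imp, selection_config(include_ids = paste0("m", 1:4),
                                                 seed = 1))
  expect_equal(primary$marker_ids, paste0("m", 1:4))
  # audit of the primary set alone: s1/s2 unresolved on observed data
  aud <- verify_core(gm, paste0("m", 1:4), m = 1)
  expect_false(aud$pass)
  expect_equal(aud$offending$sample_a, "s1")
  expect_true(aud$ledger$imputed_only_diff[aud$ledger$a == 1 & aud$ledger$b == 2])
  # recovery adds the only marker observed and differing in that pair
  final <- recover_missing(gm, imp, primary, selection_config(seed = 1))
  expect_equal(setdiff(final$marker_ids, primary$marker_ids), "m5")
  expect_true(verify_core(gm, final, 1)$pass)
  # brute force: m5 is the unique single-marker rescue
  rescuers <- which(sapply(1:5, function(j) brute_pair_diff(g, 1, 2, j) > 0))
  expect_equal(rescuers, 5L)
})

test_that("m = 2 forces a second observed difference per pair", {
  # s1/s2 differ at exactly two markers (m4, m5); a core holding only m4
  # must be extended by m5 to meet the two-marker guarantee
  g <- rbind(s1 = c(0L, 0L, 0L, 0L, 0L),
             s2 = c(0L, 0L, 0L, 1L, 1L),
             s3 = c(0L, 1L, 1L, 1L, 0L),
             s4 = c(1L, 0L, 1L, 1L, 0L))
  gm <- rand_gm(4, 5, seed = 7); gm$geno <- g
  imp <- impute_major(gm)
  cfg <- selection_config(m = 2, include_ids = c("m1", "m2", "m4"), seed = 1)
  primary <- greedy_select(imp, cfg)
  final <- recover_missing(gm, imp, primary, cfg)
  expect_true("m5" %in% final$marker_ids)
  expect_true(verify_core(gm, final, 2)$pass)
  # pairs below two observed differences anywhere are exempt, not looped on
  expect_true(all(final$unresolved_pairs$observed_diff < 2))
})

test_that("verify_core is a faithful independent auditor", {
  gm <- rand_gm(12, 30, miss = 0.05, seed = 8)
  core <- run_pipeline(gm)$best
  expect_true(verify_core(gm, core)$pass)
  # deleting one marker from a minimal panel breaks at least one pair
  g <- cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L), c(0L, 0L, 0L, 1L))
  gm2 <- rand_gm(4, 3, seed = 9); gm2$geno <- g
  expect_false(verify_core(gm2, c("m1"), 1)$pass)
  # an empty core on distinguishable samples fails
  expect_false(verify_core(gm2, character(0), 1)$pass)
  expect_error(verify_core(gm2, "ghost", 1), class = "snpcore_validation_error")
})

test_that("multi-run best-of and candidate alternatives are as recomputed", {
  gm <- rand_gm(40, 120, miss = 0.1, seed = 10)
  run <- run_pipeline(gm, selection_config(c = 5, seed = 3))
  single <- sapply(0:4, function(k)
    length(run_pipeline(gm, selection_config(seed = 3 + k))$best$marker_ids))
  expect_equal(run$sizes, single)
  expect_equal(length(run$best$marker_ids), min(single))

  # x = 3: per-round alternatives are the top Shannon scorers by brute force
  imp <- impute_major(gm)
  core <- greedy_select(imp, selection_config(x = 3, seed = 1))
  g <- geno_codes(imp)
  alts1 <- core$alternatives[[1]]
  expect_lte(nrow(alts1), 3L)
  H_all <- apply(g, 2, function(col) {
    f <- table(col) / length(col)
    -sum(f * log(f))
  })
  poly <- apply(g, 2, function(col) length(unique(col)) > 1)
  top <- sort(H_all[poly], decreasing = TRUE)[seq_len(3)]
  expect_equal(sort(alts1$shannon, decreasing = TRUE), unname(top),
               tolerance = 1e-12)
  expect_true(core$marker_ids[1] %in% alts1$marker_id)
})
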