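test_that("read_vcf masks heterozygotes and encodes homozygotes", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_raw_vcf(f, c("sA", "sB", "sC"), c(
    "chr1\t100\tv1\tA\tG\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\tv2\tC\tT\t.\t.\t.\tGT\t1|1\t./.\t0|0"))
  gm <- read_vcf(f)
  expect_equal(dim(gm), c(3L, 2L))
  expect_equal(unname(gm$geno[, "v1"]), c(0L, NA, 1L))   # het masked
  expect_equal(unname(gm$geno[, "v2"]), c(1L, NA, 0L))   # phased separators
  expect_equal(gm$samples, c("sA", "sB", "sC"))
  expect_error(read_vcf(f, het_as_missing = FALSE),
               class = "snpcore_validation_error")
})

test_that("non-biallelic-SNP records are skipped with a count", {
  f <- withr::local_tempfile(fileext = ".vcf")
  recs <- c("chr1\t100\tv1\tA\tG\t.\t.\t.\tGT\t0/0\t1/1",
            "chr1\t200\tv2\tA\tG,T\t.\t.\t.\tGT\t0/0\t1/1",  # triallelic
            "chr1\t300\tv3\tA\tG\t.\t.\t.\tGT\t1/1\t0/0",
            "chr1\t400\tv4\tAT\tA\t.\t.\t.\tGT\t0/0\t1/1",   # indel
            "chr1\t500\tv5\tC\tT\t.\t.\t.\tGT\t0/0\t0/0")
  write_raw_vcf(f, c("sA", "sB"), recs)
  expect_message(gm <- read_vcf(f), "skipped 2")
  expect_equal(ncol(gm$geno), 3L)
  expect_equal(attr(gm, "skipped"), 2L)
  expect_equal(gm$markers$id, c("v1", "v3", "v5"))
})

test_that("read_vcf error paths: missing file, no SNPs, duplicate samples", {
  expect_error(read_vcf(file.path(tempdir(), "nope.vcf")),
               class = "snpcore_io_error")
  f <- withr::local_tempfile(fileext = ".vcf")
  write_raw_vcf(f, "sA", "chr1\t100\tv1\tA\tG,T\t.\t.\t.\tGT\t0/0")
  expect_error(suppressWarnings(read_vcf(f)), class = "snpcore_validation_error")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_raw_vcf(f2, c("sA", "sA"), "chr1\t100\tv1\tA\tG\t.\t.\t.\tGT\t0/0\t1/1")
  expect_error(read_vcf(f2), class = "snpcore_validation_error")
})

test_that("write_vcf encodes codes and round-trips cell-for-cell", {
  # tiny encoding checks
  gm1 <- geno_matrix(matrix(0L, 1, 1),
                     data.frame(id = "v1", chrom = "chr1", pos = 100L,
                                ref = "A", alt = "G"), samples = "sA")
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm1, f)
  lines <- readLines(f)
  expect_match(lines[length(lines)], "GT\t0/0$")

  gm2 <- geno_matrix(matrix(c(0L, 1L, NA, 1L), 2, 2),
                     data.frame(id = c("v1", "v2"), chrom = "chr1",
                                pos = c(100L, 200L), ref = "A", alt = "G"),
                     samples = c("sA", "sB"))
  write_vcf(gm2, f)
  expect_true(any(grepl("\\./\\.", readLines(f))))

  # round trip on a random 50 x 200 matrix with missing cells
  gm <- rand_gm(50, 200, miss = 0.1, seed = 9)
  write_vcf(gm, f)
  expect_true(read_vcf(f) == gm)
})

test_that("missingness filter removes samples first, then markers, preserving order", {
  # one sample missing both calls (rate 1.0 >= 0.5) is removed
  g <- matrix(c(0L, 1L, 0L, NA, 1L, 0L, NA, NA), 4, 2)
  g[4, ] <- NA
  gm <- rand_gm(4, 2, seed = 1); gm$geno <- g  # reuse metadata
  res <- filter_by_missingness(gm)
  expect_equal(res$matrix$samples, gm$samples[rowMeans(is.na(g)) < 0.5])
  expect_true(all(res$report$samples_removed$missing_rate >= 0.5))

  # marker missing in 1 of 10 retained samples (rate 0.1 < 0.2) is kept
  gm2 <- rand_gm(10, 3, seed = 2)
  gm2$geno[1, 2] <- NA
  res2 <- filter_by_missingness(gm2)
  expect_true("m2" %in% res2$matrix$markers$id)

  # planted 10 x 10 pattern: removal sets match an independent recount
  gm3 <- rand_gm(10, 10, miss = 0.25, seed = 3)
  res3 <- filter_by_missingness(gm3, 0.4, 0.3)
  s_rate <- sapply(seq_len(10), function(i) mean(is.na(gm3$geno[i, ])))
  keep_s <- which(s_rate < 0.4)
  m_rate <- sapply(seq_len(10), function(j) mean(is.na(gm3$geno[keep_s, j])))
  expect_equal(res3$matrix$samples, gm3$samples[keep_s])
  expect_equal(res3$matrix$markers$id, gm3$markers$id[m_rate < 0.3])
  expect_equal(res3$report$markers_removed$marker, gm3$markers$id[m_rate >= 0.3])
  # post-filter invariant: every retained unit is under its threshold
  expect_true(all(colMeans(is.na(res3$matrix$geno)) < 0.3))
})

test_that("filter errors when a threshold removes everything", {
  gm <- rand_gm(3, 3, seed = 4)
  expect_error(filter_by_missingness(gm, 0, 0.2),
               class = "snpcore_validation_error")
})

test_that("major-homozygote imputation fills only missing cells, ties to REF", {
  g <- matrix(c(0L, 0L, 1L, NA,   # majority REF
                0L, 1L, NA, NA,   # tie 1:1 -> REF
                1L, 1L, 1L, 0L),  # nothing missing
              4, 3)
  gm <- rand_gm(4, 3, seed = 5); gm$geno <- g
  imp <- impute_major(gm)
  expect_equal(unname(imp$base$geno[4, 1]), 0L)
  expect_equal(unname(imp$base$geno[3:4, 2]), c(0L, 0L))
  expect_false(anyNA(imp$base$geno))
  expect_equal(imp$imputed_mask, is.na(g), ignore_attr = TRUE)
  # untouched where observed
  expect_equal(imp$base$geno[!is.na(g)], g[!is.na(g)])

  # count conservation on a random matrix with ~10% planted missing
  gm2 <- rand_gm(30, 50, miss = 0.1, seed = 6)
  imp2 <- impute_major(gm2)
  expect_equal(sum(imp2$imputed_mask), sum(is.na(gm2$geno)))

  # all-missing marker is an error naming the marker
  gm3 <- rand_gm(3, 2, seed = 7)
  gm3$geno[, 2] <- NA
  expect_error(impute_major(gm3), "m2", class = "snpcore_validation_error")
})

test_that("marker list reader strips comments and blanks", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# panel", "m1", "", "m2  # trailing", "  m3"), f)
  expect_equal(read_marker_list(f), c("m1", "m2", "m3"))
})
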