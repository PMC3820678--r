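test_that("read_promoters derives strand-aware -1000..+500 regions", {
  cat <- read_promoters(toy_catalog_bed())
  expect_s3_class(cat, "promoter_catalog")
  pA <- cat[promoter_id == "pA"]
  expect_equal(pA$tss, 10000L)
  expect_equal(c(pA$region_start, pA$region_end), c(9000L, 10500L))
  # minus strand: relative r maps to genomic tss - r
  pB <- cat[promoter_id == "pB"]
  expect_equal(c(pB$region_start, pB$region_end), c(49501L, 51001L))
  expect_true(all(cat$region_end - cat$region_start == 1500L))
})

test_that("read_promoters rejects malformed input", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.bed")
  writeLines(c("chr1\t100\t101\tp1\t0\t+", "chr1\t200"), bad)
  expect_error(read_promoters(bad), "line 2")
  writeLines(c("chr1\t100\t101\tp1\t0\t."), bad)
  expect_error(read_promoters(bad), "strand")
  writeLines(c("chr1\t100\t101\tp1\t0\t+",
               "chr2\t100\t101\tp1\t0\t+"), bad)
  expect_error(read_promoters(bad), "duplicate")
})

test_that("longest_unsequenced_run finds maximal N runs", {
  s151 <- paste0("ACGT", strrep("N", 151), "ACGT")
  s150 <- paste0("ACGT", strrep("N", 150), "ACGT")
  expect_equal(unname(longest_unsequenced_run(c(s151, s150, "ACGTACGT"))),
               c(151L, 150L, 0L))
  # several runs: the longest wins
  multi <- paste0("NN", "ACGT", strrep("N", 7), "ACGT", "NNN")
  expect_equal(unname(longest_unsequenced_run(multi)), 7L)
  expect_error(longest_unsequenced_run(""), "empty")
})

test_that("duplicated_window_index honours the >=10-others boundary", {
  set.seed(1)
  block <- random_seq(150)
  mk <- function(n_with_block) {
    seqs <- vapply(1:20, function(i) random_seq(400), character(1))
    names(seqs) <- sprintf("p%02d", 1:20)
    for (i in seq_len(n_with_block)) {
      seqs[i] <- paste0(substr(seqs[i], 1, 100), block,
                        substr(seqs[i], 251, 400))
    }
    seqs
  }
  # 11 sharers: each shares with 10 others -> all flagged
  expect_equal(duplicated_window_index(mk(11)), sprintf("p%02d", 1:11))
  # 10 sharers: each shares with only 9 others -> none flagged
  expect_equal(duplicated_window_index(mk(10)), character(0))
  # reverse-complemented copies still count as sharing
  seqs <- mk(11)
  rcfix <- chartr("ACGT", "TGCA",
                  paste(rev(strsplit(seqs[[1]], "")[[1]]), collapse = ""))
  seqs[1] <- rcfix
  expect_true("p01" %in% duplicated_window_index(seqs))
})

test_that("duplicated_window_index matches the all-pairs brute force", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(10:40, 1)
    seqs <- vapply(seq_len(n), function(i)
      random_seq(sample(200:600, 1)), character(1))
    names(seqs) <- sprintf("p%03d", seq_len(n))
    # plant a shared block in a random subset to make hits likely
    block <- random_seq(60)
    k <- sample(3:8, 1)
    for (i in sample(n, k)) {
      seqs[i] <- paste0(block, substr(seqs[i], 61, nchar(seqs[i])))
    }
    for (min_other in c(2, k - 1)) {
      expect_equal(
        duplicated_window_index(seqs, window = 60, min_other = min_other),
        oracle_dup_windows(seqs, window = 60, min_other = min_other),
        info = sprintf("seed %d min_other %d", seed, min_other))
    }
  }
})

test_that("apply_promoter_filters combines the three rules", {
  set.seed(2)
  n <- 10
  cat <- read_promoters({
    dir <- withr::local_tempdir()
    p <- file.path(dir, "f.bed")
    writeLines(sprintf("%s\t%d\t%d\tp%02d\t0\t+",
                       c("chrX", "chrx", rep("chr1", 8)),
                       (1:n) * 10000, (1:n) * 10000 + 1, 1:n), p)
    p
  })
  seqs <- vapply(1:n, function(i) random_seq(1500), character(1))
  names(seqs) <- sprintf("p%02d", 1:n)
  # one N-run promoter (an autosomal one)
  seqs["p03"] <- paste0(substr(seqs["p03"], 1, 100), strrep("N", 151),
                        substr(seqs["p03"], 252, 1500))
  out <- apply_promoter_filters(cat, seqs)
  expect_equal(out$report$n_excluded_sex, 2L)
  expect_equal(out$report$n_excluded_unsequenced, 1L)
  expect_equal(out$report$n_retained, 7L)
  expect_setdiff <- setdiff(cat$promoter_id, out$catalog$promoter_id)
  expect_setequal(expect_setdiff, c("p01", "p02", "p03"))

  # overlap: a sex-chromosome promoter that also has an N run is excluded
  # once and counted in both per-rule sets
  seqs["p01"] <- seqs["p03"]
  out2 <- apply_promoter_filters(cat, seqs)
  expect_equal(out2$report$n_excluded_sex, 2L)
  expect_equal(out2$report$n_excluded_unsequenced, 2L)
  expect_equal(out2$report$n_retained, 7L)
  expect_true("p01" %in% out2$report$excluded_ids$sex)
  expect_true("p01" %in% out2$report$excluded_ids$unsequenced)

  # promoter without sequence is an error naming it
  expect_error(apply_promoter_filters(cat, seqs[-1]), "p01")
})

test_that("filtering is idempotent and order/renaming invariant", {
  gen <- small_bundle()
  cat <- gen$bundle$catalog
  seqs <- gen$bundle$sequences
  out1 <- apply_promoter_filters(cat, seqs)
  # idempotent
  out2 <- apply_promoter_filters(out1$catalog, seqs[out1$catalog$promoter_id])
  expect_equal(out2$report$n_retained, out1$report$n_retained)
  expect_equal(out2$catalog$promoter_id, out1$catalog$promoter_id)
  # order invariance
  perm <- sample(nrow(cat))
  cat_p <- cat[perm]
  data.table::setattr(cat_p, "class", class(cat))
  out3 <- apply_promoter_filters(cat_p, seqs)
  expect_setequal(out3$catalog$promoter_id, out1$catalog$promoter_id)
  # renaming invariance (same outcome up to the renaming)
  ren <- setNames(sprintf("q%06d", seq_len(nrow(cat))), cat$promoter_id)
  cat_r <- data.table::copy(cat)[, promoter_id := ren[promoter_id]]
  data.table::setattr(cat_r, "class", class(cat))
  seqs_r <- setNames(seqs[names(ren)], ren)
  out4 <- apply_promoter_filters(cat_r, seqs_r)
  expect_equal(sort(unname(ren[out1$catalog$promoter_id])),
               sort(out4$catalog$promoter_id))
})
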