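test_that("compile_pattern handles IUPAC, alternation and spacers", {
  tre <- compile_pattern("TGA(C/G)TCA", name = "TRE")
  expect_equal(tre$length, 7L)
  expect_equal(tre$sets[[4]], c("C", "G"))
  zr <- compile_pattern("ACTACAnnTCCCA")
  expect_equal(zr$length, 13L)
  expect_equal(zr$sets[[7]], c("A", "C", "G", "T"))
  expect_equal(zr$sets[[8]], c("A", "C", "G", "T"))
  expect_error(compile_pattern("TGAXTCA"), "invalid")
  expect_error(compile_pattern("TGA(C/GTCA"), "parenthes")
})

test_that("revcomp involutes and handles case", {
  expect_equal(revcomp("TGACGTCA"), "TGACGTCA")  # CRE is palindromic
  expect_equal(revcomp("TTGCGCAA"), "TTGCGCAA")  # so is the C/EBP site
  set.seed(31)
  s <- random_seq(60)
  expect_equal(revcomp(revcomp(s)), s)
})

with_motif_at <- function(motif, offset, len = 1500, tss_pos = 1001) {
  set.seed(37)
  s <- random_seq(len)
  # avoid accidental hits of the planted motif elsewhere is not needed for
  # targeted assertions; position is sequence index of relative `offset`
  idx <- offset + tss_pos
  paste0(substr(s, 1, idx - 1), motif,
         substr(s, idx + nchar(motif), len))
}

test_that("scan_promoter finds planted sites and respects the window", {
  cre <- compile_pattern("TGACGTCA", name = "CRE")
  s <- with_motif_at("TGACGTCA", -250)
  hits <- scan_promoter(s, cre)
  expect_true(any(hits$offset == -250 & hits$strand == "+"))
  # palindrome: the same offset is reported once
  expect_equal(sum(hits$offset == -250), 1L)
  # TRE matches via the alternation
  tre <- compile_pattern("TGA(C/G)TCA", name = "TRE")
  s2 <- with_motif_at("TGAGTCA", -100)
  expect_true(any(scan_promoter(s2, tre)$offset == -100))
  # a site outside the -500..0 window is not reported
  s3 <- with_motif_at("TGACGTCA", -700)
  expect_false(any(scan_promoter(s3, cre)$offset == -700))
  # motif spanning the window edge: plant so it straddles offset 0
  s4 <- with_motif_at("TGACGTCA", -3)
  expect_false(any(scan_promoter(s4, cre)$offset == -3))
  # N never matches, even a wildcard position
  zr <- compile_pattern("ACTACAnnTCCCA")
  s5 <- with_motif_at("ACTACANNTCCCA", -200)
  expect_false(any(scan_promoter(s5, zr)$offset == -200))
})

test_that("scanner is equivalent to the naive matcher on random 500-mers", {
  motifs <- list(compile_pattern("TGACGTCA", name = "CRE"),
                 compile_pattern("TGA(C/G)TCA", name = "TRE"),
                 compile_pattern("ACTACAnnTCCCA", name = "ZR"))
  set.seed(41)
  n_checked <- 0L
  for (i in 1:60) {
    s <- random_seq(500)
    # plant a motif in half the sequences to guarantee hits
    if (i %% 2 == 0) {
      m <- sample(c("TGACGTCA", "TGACTCA", "TGAGTCA"), 1)
      at <- sample(500 - nchar(m), 1)
      s <- paste0(substr(s, 1, at - 1), m,
                  substr(s, at + nchar(m), 500))
    }
    for (mot in motifs) {
      got <- scan_promoter(s, mot, window = c(-500, 0), tss_pos = 501L)
      want <- oracle_scan(s, mot$sets, window = c(-500, 0), tss_pos = 501L)
      expect_equal(got$offset, want$offset)
      expect_equal(got$strand, want$strand)
      n_checked <- n_checked + nrow(want)
    }
  }
  expect_gt(n_checked, 20)  # the comparison actually saw hits
})

test_that("motif_presence agrees with scan_promoter per sequence", {
  set.seed(43)
  seqs <- vapply(1:50, function(i) random_seq(1500), character(1))
  names(seqs) <- sprintf("s%02d", 1:50)
  seqs[3] <- with_motif_at("TGACGTCA", -250)
  mots <- default_motifs()[c("CRE", "CEBP", "TRE")]
  pres <- motif_presence(seqs, mots)
  for (i in seq_along(seqs)) {
    for (m in names(mots)) {
      expect_equal(unname(pres[i, m]),
                   nrow(scan_promoter(seqs[[i]], mots[[m]])) > 0,
                   info = paste(i, m))
    }
  }
})

test_that("planted CRE sites are all detected; background rate is sane", {
  cre <- compile_pattern("TGACGTCA", name = "CRE")
  set.seed(47)
  n <- 2000
  seqs <- vapply(seq_len(n), function(i) random_seq(500), character(1))
  names(seqs) <- sprintf("s%04d", seq_len(n))
  planted <- sample(n, 300)
  for (i in planted) {
    at <- sample(492, 1)
    seqs[i] <- paste0(substr(seqs[i], 1, at - 1), "TGACGTCA",
                      substr(seqs[i], at + 8, 500))
  }
  pres <- motif_presence(seqs, cre, window = c(-500, 0), tss_pos = 501L)
  expect_true(all(pres[planted, 1]))
  # false-positive rate on unplanted sequences: an 8-mer palindrome has
  # per-position hit probability 4^-8; ~493 positions, one strand set
  bg <- mean(pres[-planted, 1])
  p_exp <- 1 - (1 - 4^-8)^493
  sd_exp <- sqrt(p_exp * (1 - p_exp) / (n - 300))
  expect_lt(abs(bg - p_exp), 3 * sd_exp + 1e-12)
})

test_that("combo_enrichment counts exclusively and normalises", {
  # toy universe: 2000 promoters; a 20-promoter group where CRE+TRE
  # co-occurs at 8/20 vs 80/2000 overall -> enrichment 10
  n <- 2000
  pres <- matrix(FALSE, n, 3, dimnames = list(sprintf("p%04d", 1:n),
                                              c("CRE", "CEBP", "TRE")))
  pres[1:80, c("CRE", "TRE")] <- TRUE   # includes the 8 group members
  labs <- rep("none", n)
  labs[c(1:8, 101:112)] <- "CREB+CJUN"  # 8 with combo, 12 without
  pat <- data.table::data.table(promoter_id = rownames(pres), label = labs)
  data.table::setattr(pat, "factors", c("CREB", "CEBPB", "CJUN"))
  r <- combo_enrichment(pres, pat, c("CRE", "TRE"), "CREB+CJUN",
                        exclusive = TRUE)
  expect_equal(r$n_group, 20L)
  expect_equal(r$n_with_combo, 8L)
  expect_equal(r$enrichment, (8 / 20) / (80 / 2000))
  # exclusivity: promoters that also carry CEBP no longer count
  pres2 <- pres; pres2[1:80, "CEBP"] <- TRUE
  r2 <- combo_enrichment(pres2, pat, c("CRE", "TRE"), "CREB+CJUN",
                         exclusive = TRUE)
  expect_equal(r2$n_with_combo, 0L)
  r3 <- combo_enrichment(pres2, pat, c("CRE", "TRE"), "CREB+CJUN",
                         exclusive = FALSE)
  expect_equal(r3$n_with_combo, 8L)
  # group = all promoters -> enrichment exactly 1
  pat_all <- data.table::copy(pat)[, label := "all"]
  data.table::setattr(pat_all, "factors", attr(pat, "factors"))
  r4 <- combo_enrichment(pres, pat_all, c("CRE", "TRE"), "all")
  expect_equal(r4$enrichment, 1)
})

test_that("colocalization_ratio normalises group rate by universe rate", {
  n <- 300
  pres <- matrix(FALSE, n, 2, dimnames = list(sprintf("p%03d", 1:n),
                                              c("CRE", "CEBP")))
  pres[1:30, ] <- TRUE  # 30/300 universe co-occurrence
  grp <- sprintf("p%03d", c(1:3, 31:37))  # 3/10 in the group
  expect_equal(colocalization_ratio(pres, c("CRE", "CEBP"), grp), 3.0)
  expect_equal(colocalization_ratio(pres, c("CRE", "CEBP"),
                                    rownames(pres)), 1.0)
  pres0 <- pres; pres0[] <- FALSE
  expect_error(colocalization_ratio(pres0, c("CRE", "CEBP"), grp),
               "co-occurrence")
})
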