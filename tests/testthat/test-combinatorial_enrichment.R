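mk_patterns <- function(labels, factors = c("CREB", "CEBPB", "CJUN")) {
  dt <- data.table::data.table(promoter_id = sprintf("p%04d",
                                                     seq_along(labels)))
  for (f in factors) {
    dt[[f]] <- vapply(strsplit(labels, "+", fixed = TRUE),
                      function(p) f %in% p, logical(1))
  }
  dt$label <- labels
  data.table::setattr(dt, "factors", factors)
  dt
}

test_that("assign_patterns builds canonical labels", {
  prof <- data.table::data.table(
    promoter_id = rep(c("a", "b", "c"), each = 3),
    factor = rep(c("CREB", "CEBPB", "CJUN"), 3),
    condition = "diff",
    mean_enrichment = 0,
    bound = c(TRUE, TRUE, FALSE,  FALSE, FALSE, FALSE,  TRUE, TRUE, TRUE))
  pat <- assign_patterns(prof)
  expect_equal(pat[promoter_id == "a"]$label, "CREB+CEBPB")
  expect_equal(pat[promoter_id == "b"]$label, "none")
  expect_equal(pat[promoter_id == "c"]$label, "CREB+CEBPB+CJUN")
})

test_that("euler_counts conserves the universe and marginals", {
  labs <- pattern_labels()
  pat <- mk_patterns(labs)  # one promoter per pattern
  eu <- euler_counts(pat)
  expect_equal(sum(eu$pattern_counts), 8L)
  expect_equal(unname(eu$factor_totals), c(4L, 4L, 4L))
  # empty universe
  eu0 <- euler_counts(mk_patterns(character(0)))
  expect_equal(sum(eu0$pattern_counts), 0L)
  # bigger random assignment still conserves
  set.seed(9)
  pat2 <- mk_patterns(sample(labs, 500, replace = TRUE))
  eu2 <- euler_counts(pat2)
  expect_equal(sum(eu2$pattern_counts), 500L)
  for (f in c("CREB", "CEBPB", "CJUN")) {
    expect_equal(unname(eu2$factor_totals[f]),
                 sum(grepl(f, names(eu2$pattern_counts))
                     * eu2$pattern_counts))
  }
})

test_that("group fractions, expectation and ratio follow the definitions", {
  labs <- c(rep("CEBPB+CJUN", 50), rep("none", 50))
  pat <- mk_patterns(labs)
  calls <- data.table::data.table(
    promoter_id = pat$promoter_id,
    status = c(rep("induced", 10), rep("unchanged", 90)))
  g <- group_status_fraction(pat, "CEBPB+CJUN", calls, "induced")
  expect_equal(g$fraction, 0.20)
  g0 <- group_status_fraction(pat, "none", calls, "induced")
  expect_equal(g0$fraction, 0)
  # the published arithmetic: 797 induced of 20,328 promoters, a group at
  # 20% induced is five-fold enriched over chance
  exp_frac <- expected_fraction(797, 20328)
  expect_equal(round(exp_frac, 4), 0.0392)
  expect_equal(round(enrichment_ratio(0.20, exp_frac), 2), 5.10)
  expect_equal(enrichment_ratio(exp_frac, exp_frac), 1)
  expect_equal(enrichment_ratio(0, exp_frac), 0)
  expect_error(enrichment_ratio(0.2, 0), "> 0")
})

test_that("chi_square_gof matches the hand formula and stats::chisq.test", {
  g <- chi_square_gof(c(30, 70), c(20, 80))
  expect_equal(g$chi2, 6.25)
  expect_equal(round(g$p, 4), 0.0124)
  expect_equal(chi_square_gof(c(25, 75), c(25, 75))$chi2, 0)
  expect_equal(chi_square_gof(c(25, 75), c(25, 75))$p, 1)
  expect_equal(chi_square_gof(c(0, 100), c(50, 50))$chi2, 100)
  # against the stock implementation on random tables
  set.seed(13)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    p <- rexp(k); p <- p / sum(p)
    o <- as.vector(stats::rmultinom(1, 500, p))
    ref <- suppressWarnings(stats::chisq.test(o, p = p))
    g <- chi_square_gof(o, 500 * p)
    expect_equal(g$chi2, unname(ref$statistic))
    expect_equal(g$p, unname(ref$p.value))
  }
  expect_error(chi_square_gof(c(1, 2), c(0, 3)), "pool")
  expect_error(chi_square_gof(c(10, 10), c(5, 5)), "totals")
})

test_that("two_sample_ttest matches textbook and stats::t.test", {
  r <- two_sample_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(round(r$t, 3), -3.674)
  expect_equal(r$df, 4)
  expect_equal(round(r$p, 4), 0.0213)  # frozen from the textbook oracle
  expect_equal(r$p, oracle_pooled_t(c(1, 2, 3), c(4, 5, 6))$p)
  # same values -> t 0, p 1
  r0 <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # swap flips sign, keeps p
  r2 <- two_sample_ttest(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  set.seed(17)
  x <- rnorm(20); y <- rnorm(15, 0.5)
  o <- oracle_pooled_t(x, y)
  r3 <- two_sample_ttest(x, y)
  expect_equal(r3$t, o$t)
  expect_equal(r3$p, o$p)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(r3$t, unname(ref$statistic))
  expect_equal(r3$p, ref$p.value)
  refw <- stats::t.test(x, y)
  rw <- two_sample_ttest(x, y, var_equal = FALSE)
  expect_equal(rw$t, unname(refw$statistic))
  expect_equal(rw$p, refw$p.value)
  expect_error(two_sample_ttest(c(1, 1), c(1, 1)), "variance")
})

test_that("percentile_summary matches a sort-and-interpolate oracle", {
  expect_equal(unname(percentile_summary(5)), c(5, 5, 5))
  expect_equal(unname(percentile_summary(0:100)[2]), 50)
  set.seed(19)
  x <- rnorm(20)
  expect_equal(unname(percentile_summary(x)),
               oracle_quantile(x, c(0.15, 0.5, 0.85)))
  q <- percentile_summary(x)
  expect_true(q[1] <= q[2] && q[2] <= q[3])
})

test_that("group_enrichment_table conserves counts; all-group ratio is 1", {
  set.seed(23)
  labs <- sample(pattern_labels(), 400, replace = TRUE)
  pat <- mk_patterns(labs)
  calls <- data.table::data.table(
    promoter_id = pat$promoter_id,
    status = sample(c("induced", "repressed", "unchanged"), 400,
                    replace = TRUE, prob = c(0.1, 0.1, 0.8)))
  tab <- group_enrichment_table(pat, calls)
  for (st in c("induced", "repressed")) {
    sub <- tab[status == st]
    expect_equal(sum(sub$n_group), 400L)
    expect_equal(sum(sub$n_status), sum(calls$status == st))
  }
  # the "all promoters" pseudo-group: fraction equals expectation exactly
  all_pat <- data.table::copy(pat)[, label := "all"]
  data.table::setattr(all_pat, "factors", attr(pat, "factors"))
  g <- group_status_fraction(all_pat, "all", calls, "induced")
  expect_equal(enrichment_ratio(
    g$fraction, expected_fraction(sum(calls$status == "induced"), 400)), 1)
})

test_that("chi_square_gof agrees with a multinomial Monte-Carlo null", {
  # regime where the chi-square approximation applies (large expected
  # counts); 1e5 draws from the 2-cell multinomial null
  n <- 100000L
  p0 <- 0.2
  e <- c(p0, 1 - p0) * n
  o1 <- round(e[1] + 2.1 * sqrt(n * p0 * (1 - p0)))
  g <- chi_square_gof(c(o1, n - o1), e)
  set.seed(29)
  draws <- stats::rbinom(1e5, n, p0)
  stat <- (draws - e[1])^2 / e[1] + (n - draws - e[2])^2 / e[2]
  p_mc <- mean(stat >= g$chi2)
  se <- sqrt(p_mc * (1 - p_mc) / 1e5)
  expect_lt(abs(g$p - p_mc), 2 * se + 1e-12)
})
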