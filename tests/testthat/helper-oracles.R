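# Independent oracles, deliberately written as plain brute force so they do
# not share code paths with the package implementations they check.

# all-pairs exact substring sharing: promoter flagged when any window-length
# substring (either strand) occurs in >= min_other other promoters
oracle_dup_windows <- function(seqs, window = 150L, min_other = 10L) {
  rc <- function(s) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  subs <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < window) return(character(0))
    w <- vapply(seq_len(L - window + 1L),
                function(i) substr(s, i, i + window - 1L), character(1))
    w <- w[!grepl("N", w)]
    unique(c(w, vapply(w, rc, character(1))))
  })
  flagged <- vapply(seq_along(seqs), function(i) {
    others <- vapply(seq_along(seqs)[-i], function(j)
      any(subs[[i]] %in% subs[[j]]), logical(1))
    sum(others) >= min_other
  }, logical(1))
  sort(names(seqs)[flagged])
}

# naive per-position degenerate matcher over both strands with the same
# same-offset dedup rule as the scanner contract
oracle_scan <- function(seq, sets, window = c(-500, 0), tss_pos = 1001L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rcsets <- rev(lapply(sets, function(s) unname(comp[s])))
  s <- strsplit(toupper(seq), "")[[1]]
  i1 <- window[1] + tss_pos
  i2 <- window[2] + tss_pos - 1L
  w <- s[i1:i2]
  m <- length(sets)
  match_at <- function(p, ss) {
    all(vapply(seq_len(m), function(j) w[p + j - 1L] %in% ss[[j]],
               logical(1)))
  }
  npos <- length(w) - m + 1L
  if (npos < 1L) return(data.frame(offset = integer(0),
                                   strand = character(0)))
  fwd <- which(vapply(seq_len(npos), match_at, logical(1), ss = sets))
  rev_ <- which(vapply(seq_len(npos), match_at, logical(1), ss = rcsets))
  rev_ <- setdiff(rev_, fwd)
  out <- data.frame(
    offset = window[1] + c(fwd, rev_) - 1L,
    strand = rep(c("+", "-"), c(length(fwd), length(rev_))))
  out[order(out$offset), , drop = FALSE]
}

# textbook pooled two-sample t
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# sort-and-interpolate quantile (the type-7 scheme, from first principles)
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
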