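#' Canonical occupancy-pattern labels for a factor set
#'
#' The 2^k boolean combinations of the ordered factor set, labelled by
#' joining the bound factors with `+` (`"none"` when no factor is bound),
#' in a fixed canonical order (none, singles, pairs, ..., all).
#'
#' @param factors ordered character vector of factor names (default the
#'   CREB / C/EBPbeta / c-Jun triple).
#' @return character vector of the 2^k labels.
#' @export
pattern_labels <- function(factors = c("CREB", "CEBPB", "CJUN")) {
  labs <- "none"
  for (size in seq_along(factors)) {
    labs <- c(labs, utils::combn(factors, size, paste, collapse = "+"))
  }
  labs
}

#' Assign each promoter its transcription-factor occupancy pattern
#'
#' @param profiles output of [binding_profiles()].
#' @param factors ordered factor set (3 factors for the 2^3 patterns).
#' @param condition condition whose binding calls define the pattern
#'   (default `"diff"`, differentiated keratinocytes).
#' @return `data.table` with `promoter_id`, one logical column per factor
#'   and the canonical `label`.  Promoters missing a call for any factor
#'   are dropped (count in attribute `n_dropped`).
#' @export
assign_patterns <- function(profiles, factors = c("CREB", "CEBPB", "CJUN"),
                            condition = "diff") {
  cond <- condition
  sub <- profiles[factor %in% factors & condition == cond]
  miss <- setdiff(factors, unique(sub$factor))
  if (length(miss)) stop("no binding calls for factor(s): ",
                         paste(miss, collapse = ", "))
  w <- dcast(sub, promoter_id ~ factor, value.var = "bound")
  n0 <- nrow(w)
  ok <- stats::complete.cases(w[, ..factors])
  w <- w[ok]
  bm <- as.matrix(w[, ..factors])
  lab <- apply(bm, 1, function(b) {
    if (!any(b)) "none" else paste(factors[b], collapse = "+")
  })
  out <- cbind(data.table(promoter_id = w$promoter_id), w[, ..factors])
  out[, label := lab]
  setattr(out, "factors", factors)
  setattr(out, "n_dropped", n0 - nrow(w))
  out[]
}

#' Pattern counts and single-factor totals (Euler-diagram numbers)
#'
#' @param patterns output of [assign_patterns()].
#' @return list with `pattern_counts` (named integer vector over all 2^k
#'   canonical labels, zeros included) and `factor_totals` (promoters bound
#'   by each factor, i.e. sums of the patterns containing it).
#' @export
euler_counts <- function(patterns) {
  factors <- attr(patterns, "factors")
  labs <- pattern_labels(factors)
  tab <- table(base::factor(patterns$label, levels = labs))
  counts <- setNames(as.integer(tab), labs)
  totals <- vapply(factors, function(f)
    sum(vapply(patterns[[f]], isTRUE, logical(1))), integer(1))
  list(pattern_counts = counts, factor_totals = totals)
}

#' Fraction of a pattern group carrying a status
#'
#' @param patterns output of [assign_patterns()].
#' @param label one canonical pattern label.
#' @param calls `data.table` with `promoter_id` and `status`.
#' @param status status of interest (e.g. `"induced"`).
#' @return list `n_group`, `n_status`, `fraction` (`NA` fraction, flagged
#'   via `empty = TRUE`, when the group is empty).
#' @export
group_status_fraction <- function(patterns, label, calls, status) {
  lab <- label
  ids <- patterns$promoter_id[patterns$label == lab]
  sub <- calls[calls$promoter_id %in% ids]
  n_group <- nrow(sub)
  n_status <- sum(sub$status == status, na.rm = TRUE)
  list(n_group = n_group, n_status = n_status,
       fraction = if (n_group > 0) n_status / n_group else NA_real_,
       empty = n_group == 0)
}

#' Universe-wide ("expected by chance") status fraction
#'
#' @param n_status number of promoters with the status in the whole
#'   universe.
#' @param n_universe universe size.
#' @return `n_status / n_universe`.
#' @export
expected_fraction <- function(n_status, n_universe) {
  if (n_universe <= 0) stop("empty universe")
  n_status / n_universe
}

#' Enrichment ratio of an observed fraction over the chance expectation
#'
#' @param fraction observed group fraction.
#' @param expected chance (universe-wide) fraction; must be > 0.
#' @return `fraction / expected`.
#' @export
enrichment_ratio <- function(fraction, expected) {
  if (any(expected <= 0)) stop("expected fraction must be > 0")
  fraction / expected
}

#' Chi-square goodness of fit of observed counts against expected counts
#'
#' The classic statistic `sum((o - e)^2 / e)` with an upper-tail p-value on
#' k - 1 degrees of freedom, i.e. the semantics of a spreadsheet CHITEST of
#' observed against expected counts derived from the total number of
#' events.
#'
#' @param observed,expected numeric vectors of equal length >= 2 with equal
#'   totals (within rounding); all expected counts must be > 0.
#' @return list `chi2`, `df`, `p`.
#' @export
chi_square_gof <- function(observed, expected) {
  if (length(observed) != length(expected) || length(observed) < 2) {
    stop("observed and expected must have equal length >= 2")
  }
  if (any(expected <= 0)) {
    stop("zero or negative expected cell; pool sparse categories first")
  }
  if (abs(sum(observed) - sum(expected)) >
      max(0.5, 1e-6 * abs(sum(observed)))) {
    stop("observed and expected totals differ beyond rounding")
  }
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Two-sample t test (pooled variance by default)
#'
#' Pooled-variance (spreadsheet TTEST type 2) or Welch two-sample t
#' statistic with a two-tailed p-value.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param var_equal pooled variance when `TRUE` (default), Welch otherwise.
#' @return list `t`, `df`, `p`.
#' @export
two_sample_ttest <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each sample needs >= 2 values")
  vx <- stats::var(x); vy <- stats::var(y)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    if (sp2 <= 0) stop("degenerate (zero) pooled variance")
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    if (vx <= 0 && vy <= 0) stop("degenerate (zero) variance")
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mean(x) - mean(y)) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Percentile summary of a per-promoter quantity
#'
#' Linear-interpolation (type 7) quantiles, by default the 15th, 50th and
#' 85th percentiles used for the binding-distribution bar plots.
#'
#' @param values numeric vector (length >= 1, NAs removed).
#' @param probs probabilities (default `c(0.15, 0.5, 0.85)`).
#' @return named numeric vector of quantiles.
#' @export
percentile_summary <- function(values, probs = c(0.15, 0.5, 0.85)) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values")
  quantile(values, probs = probs, type = 7, names = TRUE)
}

#' Per-pattern enrichment of differential statuses
#'
#' For every occupancy pattern and every status, computes the group size,
#' the status count and fraction, the chance expectation (the universe-wide
#' status rate), the enrichment ratio and a chi-square goodness-of-fit
#' p-value of the observed (status, non-status) split against the chance
#' split.  The universe is the set of promoters present in both `patterns`
#' and `calls`.
#'
#' @param patterns output of [assign_patterns()].
#' @param calls `data.table` with `promoter_id` and `status`.
#' @param statuses statuses to tabulate (default induced and repressed).
#' @param p_adjust add a Benjamini-Hochberg adjusted `p_adj` column
#'   (default `FALSE`: raw per-group p-values are reported).
#' @return `data.table` with one row per pattern x status:
#'   `label`, `status`, `n_group`, `n_status`, `fraction`,
#'   `expected_fraction`, `enrichment_ratio`, `chi2`, `p` (and `p_adj`
#'   when requested).
#' @export
group_enrichment_table <- function(patterns, calls,
                                   statuses = c("induced", "repressed"),
                                   p_adjust = FALSE) {
  factors <- attr(patterns, "factors")
  labs <- pattern_labels(factors)
  uni <- merge(patterns[, .(promoter_id, label)],
               calls[, .(promoter_id, status)], by = "promoter_id")
  n_universe <- nrow(uni)
  if (n_universe == 0) stop("empty universe: no shared promoters")
  rows <- list()
  for (st in statuses) {
    n_tot <- sum(uni$status == st, na.rm = TRUE)
    exp_frac <- expected_fraction(n_tot, n_universe)
    for (lab in labs) {
      grp <- uni[label == lab]
      ng <- nrow(grp)
      ns <- sum(grp$status == st, na.rm = TRUE)
      frac <- if (ng > 0) ns / ng else NA_real_
      ratio <- if (ng > 0 && exp_frac > 0) frac / exp_frac else NA_real_
      if (ng > 0 && exp_frac > 0 && exp_frac < 1) {
        gof <- chi_square_gof(c(ns, ng - ns),
                              c(exp_frac * ng, (1 - exp_frac) * ng))
        chi2 <- gof$chi2; p <- gof$p
      } else {
        chi2 <- NA_real_; p <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.table(
        label = lab, status = st, n_group = ng, n_status = ns,
        fraction = frac, expected_fraction = exp_frac,
        enrichment_ratio = ratio, chi2 = chi2, p = p)
    }
  }
  out <- rbindlist(rows)
  if (isTRUE(p_adjust)) out[, p_adj := stats::p.adjust(p, method = "BH")]
  setattr(out, "n_universe", n_universe)
  out[]
}

#' Percentile summaries of a quantity per occupancy pattern
#'
#' @param patterns output of [assign_patterns()].
#' @param values `data.table` with `promoter_id` and `value`.
#' @param probs quantile probabilities (default 15/50/85).
#' @return `data.table`: `label`, `n`, one column per percentile, plus an
#'   `all` row for the whole universe.
#' @export
group_percentiles <- function(patterns, values,
                              probs = c(0.15, 0.5, 0.85)) {
  labs <- pattern_labels(attr(patterns, "factors"))
  uni <- merge(patterns[, .(promoter_id, label)], values,
               by = "promoter_id")
  mk <- function(lab, v) {
    v <- v[!is.na(v)]
    if (!length(v)) {
      q <- rep(NA_real_, length(probs))
    } else {
      q <- unname(percentile_summary(v, probs))
    }
    row <- as.list(q)
    names(row) <- paste0("p", probs * 100)
    c(list(label = lab, n = length(v)), row)
  }
  rows <- c(list(mk("all", uni$value)),
            lapply(labs, function(l) mk(l, uni[label == l]$value)))
  rbindlist(rows)[]
}
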