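#' Threshold configuration for binding and differential calls
#'
#' Defaults are the study thresholds on the log2 IP/input scale: factor
#' binding cutoffs CREB 0.4, C/EBPbeta 0.4, C/EBPalpha 0.36, c-Jun 0.36 and
#' RNA polymerase II 0.4; RNAP induction requires the differentiated-state
#' value above 0.4 *and* a differentiated-minus-undifferentiated gain above
#' 0.3 (repression mirrors this); H3K9ac uses 0.4/0.36; the mRNA call uses
#' |log2 fold change| > 0.5 (a 1.4-fold change).  The MeDIP methylation
#' cutoff is not pinned by the study design and defaults to 0.4.
#'
#' @param bind_threshold named numeric vector of per-factor binding cutoffs
#'   (log2).
#' @param rnap_level,rnap_delta RNAP differential call thresholds (log2).
#' @param h3k9ac_level,h3k9ac_delta H3K9ac differential call thresholds.
#' @param mrna_log2fc absolute log2 fold-change cutoff for mRNA calls.
#' @param medip_threshold MeDIP cutoff for the binary methylation call.
#' @return a `threshold_config` list.
#' @export
threshold_config <- function(bind_threshold = c(CREB = 0.4, CEBPB = 0.4,
                                                CEBPA = 0.36, CJUN = 0.36,
                                                RNAP = 0.4),
                             rnap_level = 0.4, rnap_delta = 0.3,
                             h3k9ac_level = 0.4, h3k9ac_delta = 0.36,
                             mrna_log2fc = 0.5, medip_threshold = 0.4) {
  stopifnot(all(is.finite(bind_threshold)), is.finite(rnap_level),
            is.finite(h3k9ac_level), is.finite(mrna_log2fc),
            is.finite(medip_threshold))
  if (rnap_delta < 0 || h3k9ac_delta < 0) {
    stop("differential deltas must be >= 0")
  }
  structure(list(bind_threshold = bind_threshold,
                 rnap_level = rnap_level, rnap_delta = rnap_delta,
                 h3k9ac_level = h3k9ac_level, h3k9ac_delta = h3k9ac_delta,
                 mrna_log2fc = mrna_log2fc,
                 medip_threshold = medip_threshold),
            class = "threshold_config")
}

#' Read one probe-level enrichment track (bedGraph)
#'
#' A track holds probe-level log2 IP/input values for one factor in one
#' condition and replicate.  bedGraph `track` header lines are skipped; the
#' probe position is the interval start.
#'
#' @param path bedGraph file (chrom, start, end, value).
#' @param factor factor name, e.g. `"CREB"`, `"RNAP"`, `"MEDIP"`.
#' @param condition `"undiff"` or `"diff"`.
#' @param replicate replicate number.
#' @return a `data.table` with columns `factor`, `condition`, `replicate`,
#'   `chrom`, `pos`, `value`.
#' @export
read_bedgraph <- function(path, factor, condition, replicate = 1L) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first)) {
    return(data.table(factor = character(0), condition = character(0),
                      replicate = integer(0), chrom = character(0),
                      pos = integer(0), value = numeric(0)))
  }
  dt <- fread(path, header = FALSE,
              skip = if (grepl("^track", first)) 1L else 0L)
  if (ncol(dt) < 4L) stop("bedGraph needs >= 4 columns: ", path)
  setnames(dt, 1:4, c("chrom", "pos", "end", "value"))
  if (!is.numeric(dt$value) || any(!is.finite(dt$value))) {
    stop("non-finite enrichment values in ", path)
  }
  if (any(dt$pos < 0)) stop("negative probe positions in ", path)
  data.table(factor = factor, condition = condition,
             replicate = as.integer(replicate),
             chrom = dt$chrom, pos = as.integer(dt$pos), value = dt$value)
}

#' Read a directory of bedGraph tracks
#'
#' Files must be named `<FACTOR>_<condition>_rep<k>.bedGraph`
#' (e.g. `CREB_diff_rep1.bedGraph`).
#'
#' @param dir directory containing the track files.
#' @return one long `data.table` of all tracks (see [read_bedgraph()]).
#' @export
read_signal_tracks <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.bedGraph$", full.names = TRUE))
  if (!length(files)) stop("no .bedGraph files in ", dir)
  parts <- regmatches(basename(files),
                      regexec("^(.+)_(undiff|diff)_rep([0-9]+)\\.bedGraph$",
                              basename(files)))
  bad <- lengths(parts) != 4L
  if (any(bad)) {
    stop("track file name not <FACTOR>_<condition>_rep<k>.bedGraph: ",
         basename(files)[bad][1])
  }
  rbindlist(lapply(seq_along(files), function(i) {
    read_bedgraph(files[i], factor = parts[[i]][2],
                  condition = parts[[i]][3],
                  replicate = as.integer(parts[[i]][4]))
  }))
}

#' Mean enrichment of one track over one promoter region
#'
#' The binding statistic: the arithmetic mean of the log2 enrichment of all
#' probes whose position falls inside the promoter's -1000..+500 region.
#'
#' @param track a track `data.table` (see [read_bedgraph()]).
#' @param promoter a single-row `promoter_catalog` subset.
#' @return the mean log2 enrichment, or `NA_real_` when no probe lies in
#'   the region (the promoter is then absent from that factor's universe).
#' @export
promoter_mean_enrichment <- function(track, promoter) {
  stopifnot(nrow(promoter) == 1L)
  inreg <- track$chrom == promoter$chrom &
    track$pos >= promoter$region_start & track$pos < promoter$region_end
  if (!any(inreg)) return(NA_real_)
  mean(track$value[inreg])
}

#' Average per-replicate promoter means
#'
#' Missing replicate values (promoter absent from a replicate's probe set)
#' are skipped; the result is missing only when all replicates are missing.
#'
#' @param values numeric vector of per-replicate means (may contain `NA`).
#' @return mean of the non-missing values, or `NA_real_`.
#' @export
average_replicates <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Per-promoter replicate-averaged mean enrichments for all tracks
#'
#' Assigns every probe to the promoter region(s) containing it, averages
#' probe values per promoter x factor x condition x replicate, then
#' averages replicates.
#'
#' @param signals long track `data.table` (see [read_signal_tracks()]).
#' @param catalog a `promoter_catalog`.
#' @return `data.table` with `promoter_id`, `factor`, `condition`,
#'   `mean_enrichment`, `n_probes` (summed over replicates).
#' @export
promoter_means <- function(signals, catalog) {
  cat2 <- catalog[, .(promoter_id, chrom, region_start, region_end)]
  hits <- signals[cat2,
                  on = .(chrom, pos >= region_start, pos < region_end),
                  .(promoter_id = i.promoter_id, factor = x.factor,
                    condition = x.condition, replicate = x.replicate,
                    value = x.value),
                  nomatch = NULL, allow.cartesian = TRUE]
  rep_means <- hits[, .(m = mean(value), n = .N),
                    by = .(promoter_id, factor, condition, replicate)]
  out <- rep_means[, .(mean_enrichment = mean(m), n_probes = sum(n)),
                   by = .(promoter_id, factor, condition)]
  setorder(out, factor, condition, promoter_id)
  out[]
}

#' Binding call for one replicate-averaged mean
#'
#' Bound means strictly greater than the factor's threshold.
#'
#' @param mean_enrichment numeric vector of promoter means (log2).
#' @param factor single factor name; must be present in
#'   `cfg$bind_threshold`.
#' @param cfg a [threshold_config()].
#' @return logical vector.
#' @export
call_binding <- function(mean_enrichment, factor, cfg = threshold_config()) {
  if (!factor %in% names(cfg$bind_threshold)) {
    stop("no binding threshold for factor: ", factor)
  }
  mean_enrichment > cfg$bind_threshold[[factor]]
}

#' Binding profiles for all promoters, factors and conditions
#'
#' @param signals long track `data.table`.
#' @param catalog a `promoter_catalog`.
#' @param cfg a [threshold_config()].
#' @return `data.table` with `promoter_id`, `factor`, `condition`,
#'   `mean_enrichment`, `n_probes` and `bound` (NA for assays without a
#'   binding threshold, e.g. H3K9AC and MEDIP).
#' @export
binding_profiles <- function(signals, catalog, cfg = threshold_config()) {
  pm <- promoter_means(signals, catalog)
  thr <- cfg$bind_threshold[pm$factor]
  pm[, bound := mean_enrichment > thr]
  pm[]
}

#' Differential (induced / repressed / unchanged) status
#'
#' Induced: the differentiated value exceeds `level` and the gain over the
#' undifferentiated value exceeds `delta`.  Repressed is the mirror image
#' (the undifferentiated value exceeds `level` and the loss exceeds
#' `delta`).  All inequalities are strict.
#'
#' @param diff,undiff numeric vectors of replicate-averaged means (log2) in
#'   the differentiated and undifferentiated condition.
#' @param level,delta thresholds (log2); `delta >= 0`.
#' @return character vector: `"induced"`, `"repressed"` or `"unchanged"`
#'   (`NA` where either input is missing).
#' @export
call_differential <- function(diff, undiff, level, delta) {
  if (!is.finite(level) || !is.finite(delta) || delta < 0) {
    stop("invalid level/delta configuration")
  }
  status <- rep(NA_character_, length(diff))
  ok <- !is.na(diff) & !is.na(undiff)
  ind <- ok & diff > level & (diff - undiff) > delta
  rep_ <- ok & undiff > level & (undiff - diff) > delta
  status[ok] <- "unchanged"
  status[ind] <- "induced"
  status[rep_] <- "repressed"
  status
}

#' Differential calls for an assay across the promoter universe
#'
#' @param profiles output of [binding_profiles()] or [promoter_means()].
#' @param assay `"RNAP"` or `"H3K9AC"`.
#' @param cfg a [threshold_config()].
#' @return `data.table` with `promoter_id`, `assay`, `diff_value`,
#'   `undiff_value`, `status`.  Promoters missing either condition are
#'   dropped (count in attribute `n_dropped`).
#' @export
differential_calls <- function(profiles, assay = c("RNAP", "H3K9AC"),
                               cfg = threshold_config()) {
  assay <- match.arg(assay)
  level <- if (assay == "RNAP") cfg$rnap_level else cfg$h3k9ac_level
  delta <- if (assay == "RNAP") cfg$rnap_delta else cfg$h3k9ac_delta
  sub <- profiles[factor == assay]
  w <- dcast(sub, promoter_id ~ condition, value.var = "mean_enrichment")
  for (cond in c("diff", "undiff")) {
    if (!cond %in% names(w)) stop("missing condition '", cond,
                                  "' for assay ", assay)
  }
  n0 <- nrow(w)
  w <- w[!is.na(diff) & !is.na(undiff)]
  out <- data.table(promoter_id = w$promoter_id, assay = assay,
                    diff_value = w$diff, undiff_value = w$undiff,
                    status = call_differential(w$diff, w$undiff, level, delta))
  setattr(out, "n_dropped", n0 - nrow(w))
  out[]
}

#' Binary promoter methylation call from MeDIP enrichment
#'
#' @param medip_mean numeric vector of replicate-averaged MeDIP means.
#' @param cfg a [threshold_config()]; the cutoff is
#'   `cfg$medip_threshold` (strict `>`).
#' @return logical vector (`NA` propagated).
#' @export
call_methylation <- function(medip_mean, cfg = threshold_config()) {
  medip_mean > cfg$medip_threshold
}
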