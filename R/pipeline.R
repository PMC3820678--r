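#' Run configuration for the end-to-end pipeline
#'
#' @param promoters promoter BED6 path.
#' @param annotations promoter annotation TSV path (optional).
#' @param sequences promoter FASTA path (optional; motif stages are skipped
#'   without it).
#' @param tracks directory of `<FACTOR>_<cond>_rep<k>.bedGraph` files.
#' @param expression expression TSV path (optional).
#' @param outdir output directory.
#' @param thresholds a [threshold_config()].
#' @param factors the occupancy factor triple (`CEBPB` or `CEBPA` variant).
#' @param motifs motif table path (default the shipped configuration).
#' @return a `run_config` list.
#' @export
run_config <- function(promoters, tracks, outdir,
                       annotations = NULL, sequences = NULL,
                       expression = NULL,
                       thresholds = threshold_config(),
                       factors = c("CREB", "CEBPB", "CJUN"),
                       motifs = NULL) {
  for (p in c(promoters, tracks,
              Filter(Negate(is.null),
                     list(annotations, sequences, expression, motifs)))) {
    if (!file.exists(p)) stop("input does not exist: ", p)
  }
  if (length(factors) != 3) stop("factor set must have exactly 3 members")
  structure(list(promoters = promoters, annotations = annotations,
                 sequences = sequences, tracks = tracks,
                 expression = expression, outdir = outdir,
                 thresholds = thresholds, factors = factors,
                 motifs = motifs),
            class = "run_config")
}

#' Analyse an in-memory dataset bundle
#'
#' The full analysis: promoter filtering, binding profiles, differential
#' RNAP / H3K9ac calls, methylation calls, expression mapping and mRNA
#' calls, occupancy patterns with Euler counts, per-pattern enrichment
#' tables (overall and stratified by methylation), per-pattern RNAP
#' binding percentiles, and motif combination / colocalization enrichment.
#'
#' @param bundle list with `catalog`, `signals` and optionally `sequences`
#'   and `expression` (see [generate_dataset()] / [read_bundle()]).
#' @param thresholds a [threshold_config()].
#' @param factors occupancy factor triple.
#' @param consensus consensus motif names used for combination statistics.
#' @return a named list of results (see the pipeline vignette).
#' @export
analyze_bundle <- function(bundle, thresholds = threshold_config(),
                           factors = c("CREB", "CEBPB", "CJUN"),
                           consensus = c("CRE", "CEBP", "TRE")) {
  res <- list()
  catalog <- bundle$catalog
  if (!is.null(bundle$sequences)) {
    filt <- apply_promoter_filters(catalog, bundle$sequences)
    catalog <- filt$catalog
    res$filter_report <- filt$report
  }
  res$profiles <- binding_profiles(bundle$signals, catalog, thresholds)
  res$rnap_calls <- differential_calls(res$profiles, "RNAP", thresholds)
  if ("H3K9AC" %in% unique(res$profiles$factor)) {
    res$h3k9ac_calls <- differential_calls(res$profiles, "H3K9AC",
                                           thresholds)
  }
  res$patterns <- assign_patterns(res$profiles, factors = factors,
                                  condition = "diff")
  res$euler <- euler_counts(res$patterns)
  res$enrichment_rnap <- group_enrichment_table(res$patterns,
                                                res$rnap_calls)
  if (!is.null(res$h3k9ac_calls)) {
    res$enrichment_h3k9ac <- group_enrichment_table(res$patterns,
                                                    res$h3k9ac_calls)
  }
  # RNAP binding percentiles per pattern (differentiated condition)
  rnap_diff <- res$profiles[factor == "RNAP" & condition == "diff",
                            .(promoter_id, value = mean_enrichment)]
  res$percentiles_rnap <- group_percentiles(res$patterns, rnap_diff)
  # expression
  if (!is.null(bundle$expression)) {
    res$expression_map <- map_expression(bundle$expression, catalog)
    res$mrna_calls <- data.table(
      promoter_id = res$expression_map$promoter_id,
      assay = "MRNA",
      status = call_mrna_change(res$expression_map$log2fc, thresholds))
    res$enrichment_mrna <- group_enrichment_table(res$patterns,
                                                  res$mrna_calls)
  }
  # methylation stratification
  if ("MEDIP" %in% unique(res$profiles$factor)) {
    medip <- res$profiles[factor == "MEDIP",
                          .(promoter_id,
                            methylated = call_methylation(mean_enrichment,
                                                          thresholds))]
    medip <- medip[!is.na(methylated)]
    res$methylation <- medip
    strat <- function(calls) {
      lapply(c(unmethylated = FALSE, methylated = TRUE), function(mm) {
        ids <- medip$promoter_id[medip$methylated == mm]
        sub <- calls[calls$promoter_id %in% ids]
        if (!nrow(sub)) return(NULL)
        group_enrichment_table(res$patterns, sub)
      })
    }
    res$enrichment_rnap_by_methylation <- strat(res$rnap_calls)
    if (!is.null(res$mrna_calls)) {
      res$enrichment_mrna_by_methylation <- strat(res$mrna_calls)
    }
    # methylated fraction per pattern vs chance
    meth_calls <- data.table(promoter_id = medip$promoter_id,
                             status = ifelse(medip$methylated,
                                             "methylated", "unmethylated"))
    res$methylation_by_pattern <-
      group_enrichment_table(res$patterns, meth_calls,
                             statuses = c("methylated", "unmethylated"))
  }
  # motifs
  if (!is.null(bundle$sequences) && length(bundle$sequences)) {
    motifs <- default_motifs()
    use <- motifs[intersect(consensus, names(motifs))]
    res$motif_presence <- motif_presence(
      bundle$sequences[catalog$promoter_id], use)
    res$motif_combo <- combo_enrichment_table(res$motif_presence,
                                              res$patterns,
                                              consensus = names(use))
    pairs <- utils::combn(names(use), 2, simplify = FALSE)
    labs <- pattern_labels(factors)
    coloc <- rbindlist(lapply(labs, function(l) {
      ids <- res$patterns$promoter_id[res$patterns$label == l]
      rbindlist(lapply(pairs, function(pr) {
        r <- tryCatch(colocalization_ratio(res$motif_presence, pr, ids),
                      error = function(e) NA_real_)
        data.table(label = l, pair = paste(pr, collapse = "+"), ratio = r)
      }))
    }))
    res$motif_colocalization <- coloc
  }
  res$universe <- catalog$promoter_id
  res
}

#' Run the whole pipeline from files and write the report bundle
#'
#' Reads the inputs named by the config, runs [analyze_bundle()] and
#' writes plain TSV/JSON reports into `outdir`: the filter report, binding
#' and differential call tables, Euler counts, per-pattern enrichment
#' tables (overall and methylation-stratified), RNAP percentile summaries,
#' motif combination and colocalization tables and a machine-readable
#' `summary.json`.  Deterministic: identical inputs give identical
#' outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, the list of result objects.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  catalog <- read_promoters(config$promoters,
                            annotations = config$annotations)
  seqs <- if (!is.null(config$sequences))
    read_promoter_sequences(config$sequences, catalog) else NULL
  signals <- read_signal_tracks(config$tracks)
  expr <- if (!is.null(config$expression))
    read_expression(config$expression) else NULL
  bundle <- list(catalog = catalog, sequences = seqs, signals = signals,
                 expression = expr)
  res <- analyze_bundle(bundle, thresholds = config$thresholds,
                        factors = config$factors)
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(x, f) fwrite(x, file.path(out, f), sep = "\t")
  if (!is.null(res$filter_report)) {
    jsonlite::write_json(res$filter_report,
                         file.path(out, "filter_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  wtsv(res$profiles, "binding_calls.tsv")
  wtsv(res$rnap_calls, "differential_rnap.tsv")
  if (!is.null(res$h3k9ac_calls)) {
    wtsv(res$h3k9ac_calls, "differential_h3k9ac.tsv")
  }
  euler <- data.table(label = names(res$euler$pattern_counts),
                      n = res$euler$pattern_counts)
  wtsv(euler, "euler_counts.tsv")
  wtsv(res$enrichment_rnap, "enrichment_rnap.tsv")
  if (!is.null(res$enrichment_h3k9ac)) {
    wtsv(res$enrichment_h3k9ac, "enrichment_h3k9ac.tsv")
  }
  if (!is.null(res$enrichment_mrna)) {
    wtsv(res$expression_map, "promoter_expression.tsv")
    wtsv(res$enrichment_mrna, "enrichment_mrna.tsv")
  }
  jsonlite::write_json(res$percentiles_rnap,
                       file.path(out, "percentiles_rnap.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  if (!is.null(res$methylation_by_pattern)) {
    wtsv(res$methylation_by_pattern, "methylation_by_pattern.tsv")
    for (stratum in c("methylated", "unmethylated")) {
      tab <- res$enrichment_rnap_by_methylation[[stratum]]
      if (!is.null(tab)) {
        wtsv(tab, sprintf("enrichment_rnap_%s.tsv", stratum))
      }
      tab <- res$enrichment_mrna_by_methylation[[stratum]]
      if (!is.null(tab)) {
        wtsv(tab, sprintf("enrichment_mrna_%s.tsv", stratum))
      }
    }
  }
  if (!is.null(res$motif_combo)) {
    wtsv(res$motif_combo, "motif_combo_enrichment.tsv")
    wtsv(res$motif_colocalization, "motif_colocalization.tsv")
  }
  summary <- list(
    n_universe = length(res$universe),
    factors = config$factors,
    filter_report = res$filter_report[
      c("n_input", "n_excluded_sex", "n_excluded_unsequenced",
        "n_excluded_duplicated", "n_retained")],
    pattern_counts = as.list(res$euler$pattern_counts),
    factor_totals = as.list(res$euler$factor_totals),
    n_rnap_induced = sum(res$rnap_calls$status == "induced"),
    n_rnap_repressed = sum(res$rnap_calls$status == "repressed"),
    n_mrna_induced = if (!is.null(res$mrna_calls))
      sum(res$mrna_calls$status == "induced", na.rm = TRUE) else NULL,
    n_mrna_repressed = if (!is.null(res$mrna_calls))
      sum(res$mrna_calls$status == "repressed", na.rm = TRUE) else NULL)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
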