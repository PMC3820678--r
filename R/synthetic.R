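#' Configuration of the synthetic dataset generator
#'
#' The defaults describe the world the analysis assumes: ~20,000 promoters
#' on the autosomes (plus decoys exercising the filters), 15 probes per
#' 1500-bp promoter region, a planted binding effect of 0.8 log2 units over
#' a 0 baseline with probe noise SD 0.25, occupancy-pattern prevalences
#' loosely mirroring the published Euler counts, and per-pattern induction
#' probabilities calibrated so that the universe-wide induction rate is
#' 0.04 while the C/EBPbeta+c-Jun (no CREB) group is induced with
#' probability 0.20 -- a planted five-fold enrichment.  Methylation is
#' depleted on CREB-bound promoters (0.10 vs 0.45).  Consensus motifs are
#' planted into the -500..0 window of bound promoters with probability 0.6
#' per factor.
#'
#' @param n_promoters number of promoters.
#' @param seed mandatory RNG seed; the bundle is a pure function of the
#'   config.
#' @param probes_per_promoter probes per promoter region.
#' @param n_replicates replicates per factor x condition track.
#' @param bound_effect planted mean log2 enrichment of a bound promoter.
#' @param baseline mean log2 enrichment of an unbound promoter.
#' @param probe_sd per-probe Gaussian noise SD (log2).
#' @param pattern_prevalence named prevalence over the 8 canonical
#'   patterns (sums to 1).
#' @param induction_prob,repression_prob named per-pattern probabilities of
#'   the induced / repressed status (used for RNAP, mRNA and H3K9ac).
#' @param meth_prob_creb,meth_prob_other methylation probability for
#'   CREB-bound vs other promoters.
#' @param motif_plant_prob named per-factor probability of planting the
#'   factor's consensus motif into a bound promoter.
#' @param frac_sex,frac_nrun fraction of sex-chromosome and long-N-run
#'   decoy promoters.
#' @param n_duplicated number of promoters sharing a planted identical
#'   150-bp block (12 > the 10-other threshold, so they are filtered).
#' @param expr_fc planted absolute mRNA log2 fold change for
#'   induced/repressed genes.
#' @param expr_noise_sd log2 noise SD on planted fold changes.
#' @param dup_row_frac fraction of genes represented by two expression
#'   rows (exercises row averaging).
#' @param constitutive_rnap probabilities that an "unchanged" promoter is
#'   constitutively RNAP-bound, given CREB binding / other TF binding / no
#'   binding.
#' @param sequences generate promoter sequences (disable to speed up runs
#'   that do not need motif analysis).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_promoters = 20000L, seed = 1L,
    probes_per_promoter = 15L, n_replicates = 2L,
    bound_effect = 0.8, baseline = 0, probe_sd = 0.25,
    pattern_prevalence = c(
      none = 0.55, CREB = 0.12, CEBPB = 0.08, CJUN = 0.05,
      "CREB+CEBPB" = 0.05, "CREB+CJUN" = 0.04, "CEBPB+CJUN" = 0.06,
      "CREB+CEBPB+CJUN" = 0.05),
    induction_prob = c(
      none = 0.02418, CREB = 0.005, CEBPB = 0.10, CJUN = 0.04,
      "CREB+CEBPB" = 0.02, "CREB+CJUN" = 0.015, "CEBPB+CJUN" = 0.20,
      "CREB+CEBPB+CJUN" = 0.05),
    repression_prob = c(
      none = 0.03, CREB = 0.10, CEBPB = 0.02, CJUN = 0.03,
      "CREB+CEBPB" = 0.08, "CREB+CJUN" = 0.08, "CEBPB+CJUN" = 0.02,
      "CREB+CEBPB+CJUN" = 0.04),
    meth_prob_creb = 0.10, meth_prob_other = 0.45,
    motif_plant_prob = c(CREB = 0.6, CEBPB = 0.6, CJUN = 0.6),
    frac_sex = 0.01, frac_nrun = 0.005, n_duplicated = 12L,
    expr_fc = 1.0, expr_noise_sd = 0.1, dup_row_frac = 0.1,
    constitutive_rnap = c(creb = 0.9, other = 0.5, none = 0.2),
    sequences = TRUE) {
  labs <- pattern_labels(c("CREB", "CEBPB", "CJUN"))
  for (v in list(pattern_prevalence, induction_prob, repression_prob)) {
    if (!setequal(names(v), labs)) {
      stop("pattern-keyed vectors must be named over: ",
           paste(labs, collapse = ", "))
    }
    if (any(v < 0 | v > 1)) stop("probabilities must be in [0, 1]")
  }
  if (abs(sum(pattern_prevalence) - 1) > 1e-8) {
    stop("pattern prevalences must sum to 1")
  }
  if (any(induction_prob[labs] + repression_prob[labs] > 1)) {
    stop("induction + repression probability exceeds 1 for some pattern")
  }
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  structure(as.list(environment())[c(
    "n_promoters", "seed", "probes_per_promoter", "n_replicates",
    "bound_effect", "baseline", "probe_sd", "pattern_prevalence",
    "induction_prob", "repression_prob", "meth_prob_creb",
    "meth_prob_other", "motif_plant_prob", "frac_sex", "frac_nrun",
    "n_duplicated", "expr_fc", "expr_noise_sd", "dup_row_frac",
    "constitutive_rnap", "sequences")],
    class = "synthetic_config")
}

#' Planted universe-wide status rate implied by a synthetic config
#'
#' The prevalence-weighted mean of the per-pattern status probabilities:
#' the "expected by chance" rate the generator plants.
#'
#' @param cfg a [synthetic_config()].
#' @param status `"induced"` or `"repressed"`.
#' @return the planted rate.
#' @export
planted_status_rate <- function(cfg, status = c("induced", "repressed")) {
  status <- match.arg(status)
  p <- if (status == "induced") cfg$induction_prob else cfg$repression_prob
  labs <- names(cfg$pattern_prevalence)
  sum(cfg$pattern_prevalence[labs] * p[labs])
}

# factor membership of a pattern label
label_has <- function(label, factor) {
  vapply(strsplit(label, "+", fixed = TRUE), function(p) factor %in% p,
         logical(1))
}

#' Generate a complete synthetic dataset bundle with its truth table
#'
#' Emits, deterministically for a given config, an in-memory bundle with a
#' promoter catalog (including sex-chromosome, long-N-run and
#' duplicated-block decoys), promoter sequences with planted consensus
#' motifs, probe-level log2 enrichment tracks for CREB / C/EBPbeta /
#' C/EBPalpha / c-Jun / RNAP / H3K9ac in both conditions plus a MeDIP
#' track, and a gene-expression table -- together with the per-promoter
#' truth (pattern, statuses, methylation, planted motif offsets).
#'
#' Probe positions are uniform over the region and shared across tracks
#' (fixed array design); probe values are the promoter's true mean plus
#' Gaussian noise.  Differential promoters have their active-condition
#' mean shifted to `level + delta + 0.1`, clearing the call thresholds
#' with margin.  C/EBPalpha binds a random half of the C/EBPbeta-bound
#' promoters.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `bundle` (list: `catalog`, `sequences`, `signals`,
#'   `expression`, `annotations`, `config`) and `truth` (`data.table`).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)
  n <- as.integer(cfg$n_promoters)
  k <- as.integer(cfg$probes_per_promoter)
  labs <- pattern_labels(c("CREB", "CEBPB", "CJUN"))

  ## -- catalog ------------------------------------------------------------
  ids <- if (n > 0) sprintf("p%06d", seq_len(n)) else character(0)
  chrom <- if (n > 0) sample(paste0("chr", 1:19), n, replace = TRUE)
           else character(0)
  n_sex <- round(cfg$frac_sex * n)
  sex_idx <- if (n_sex > 0) sample.int(n, n_sex) else integer(0)
  chrom[sex_idx] <- rep(c("chrX", "chrY"), length.out = n_sex)
  strand <- if (n > 0) sample(c("+", "-"), n, replace = TRUE)
            else character(0)
  cat_dt <- data.table(promoter_id = ids, chrom = chrom, strand = strand)
  cat_dt[, tss := 1000000L + (seq_len(.N) - 1L) * 200000L, by = chrom]
  annotations <- data.table(
    promoter_id = ids,
    genbank = sprintf("NM_%06d", seq_len(n))[seq_len(n)],
    symbol = sprintf("Gene%05d", seq_len(n))[seq_len(n)],
    unigene_cluster = sprintf("Mm.%05d", seq_len(n))[seq_len(n)],
    unigene_id = sprintf("UG%06d", seq_len(n))[seq_len(n)])
  catalog <- new_promoter_catalog(cat_dt, annotations = annotations)

  ## -- truth: patterns, statuses, methylation -----------------------------
  pattern <- if (n > 0)
    sample(labs, n, replace = TRUE, prob = cfg$pattern_prevalence[labs])
  else character(0)
  bound <- list(
    CREB = label_has(pattern, "CREB"),
    CEBPB = label_has(pattern, "CEBPB"),
    CJUN = label_has(pattern, "CJUN"))
  bound$CEBPA <- bound$CEBPB & runif(n) < 0.5
  draw_status <- function() {
    pi <- cfg$induction_prob[pattern]
    pr <- cfg$repression_prob[pattern]
    u <- runif(n)
    ifelse(u < pi, "induced", ifelse(u < pi + pr, "repressed", "unchanged"))
  }
  rnap_status <- draw_status()
  mrna_status <- draw_status()
  h3k9ac_status <- draw_status()
  methylated <- runif(n) <
    ifelse(bound$CREB, cfg$meth_prob_creb, cfg$meth_prob_other)

  ## -- true track means ---------------------------------------------------
  tf_mean <- function(b) cfg$baseline + cfg$bound_effect * b
  diff_means <- function(status, level, delta) {
    on <- level + delta + 0.1
    any_tf <- bound$CREB | bound$CEBPB | bound$CJUN
    const_p <- ifelse(bound$CREB, cfg$constitutive_rnap[["creb"]],
                      ifelse(any_tf, cfg$constitutive_rnap[["other"]],
                             cfg$constitutive_rnap[["none"]]))
    const <- runif(n) < const_p
    und <- ifelse(status == "repressed", on,
                  ifelse(status == "unchanged" & const, on, cfg$baseline))
    dif <- ifelse(status == "induced", on,
                  ifelse(status == "unchanged" & const, on, cfg$baseline))
    list(undiff = und, diff = dif)
  }
  rnap <- diff_means(rnap_status, 0.4, 0.3)
  h3k9 <- diff_means(h3k9ac_status, 0.4, 0.36)
  means <- list(
    CREB = list(undiff = tf_mean(bound$CREB), diff = tf_mean(bound$CREB)),
    CEBPB = list(undiff = tf_mean(bound$CEBPB), diff = tf_mean(bound$CEBPB)),
    CEBPA = list(undiff = tf_mean(bound$CEBPA), diff = tf_mean(bound$CEBPA)),
    CJUN = list(undiff = tf_mean(bound$CJUN), diff = tf_mean(bound$CJUN)),
    RNAP = rnap, H3K9AC = h3k9,
    MEDIP = list(diff = cfg$baseline + cfg$bound_effect * methylated))

  ## -- probe-level tracks -------------------------------------------------
  if (n > 0 && k > 0) {
    offs <- matrix(unlist(lapply(seq_len(n), function(i)
      sort(sample.int(1500L, k)))), nrow = n, byrow = TRUE)
    probe_chrom <- rep(catalog$chrom, each = k)
    probe_pos <- rep(catalog$region_start, each = k) + as.vector(t(offs)) - 1L
  } else {
    probe_chrom <- character(0)
    probe_pos <- integer(0)
  }
  tracks <- list()
  for (f in names(means)) {
    for (cond in names(means[[f]])) {
      mu <- rep(means[[f]][[cond]], each = k)
      for (r in seq_len(cfg$n_replicates)) {
        tracks[[length(tracks) + 1L]] <- data.table(
          factor = f, condition = cond, replicate = r,
          chrom = probe_chrom, pos = probe_pos,
          value = mu + rnorm(length(mu), sd = cfg$probe_sd))
      }
    }
  }
  signals <- rbindlist(tracks)

  ## -- sequences with decoys and planted motifs ---------------------------
  seqs <- NULL
  offset_cre <- rep(NA_integer_, n)
  offset_cebp <- rep(NA_integer_, n)
  offset_tre <- rep(NA_integer_, n)
  if (isTRUE(cfg$sequences) && n > 0) {
    bases <- c("A", "C", "G", "T")
    m <- matrix(sample(bases, n * 1500L, replace = TRUE), nrow = n)
    # decoys: long N run (200 bp > the 150 bp tolerance)
    n_nrun <- round(cfg$frac_nrun * n)
    nrun_idx <- if (n_nrun > 0)
      sample(setdiff(seq_len(n), sex_idx), n_nrun) else integer(0)
    if (length(nrun_idx)) m[nrun_idx, 301:500] <- "N"
    # decoys: identical 150-bp block shared by n_duplicated promoters
    nd <- min(cfg$n_duplicated, n)
    dup_idx <- if (nd > 0)
      sample(setdiff(seq_len(n), c(sex_idx, nrun_idx)), nd) else integer(0)
    if (length(dup_idx)) {
      block <- sample(bases, 150L, replace = TRUE)
      m[dup_idx, 101:250] <- matrix(rep(block, each = length(dup_idx)),
                                    nrow = length(dup_idx))
    }
    # planted motifs, in disjoint zones of the -500..0 window so plants
    # never overwrite each other (sequence index 501..1000 is -500..-1)
    plant <- function(idx, motif_chars, zone_first, zone_last) {
      starts <- if (length(idx))
        zone_first + sample.int(zone_last - zone_first + 1L, length(idx),
                                replace = TRUE) - 1L
      else integer(0)
      for (ii in seq_along(idx)) {
        m[idx[ii], starts[ii]:(starts[ii] + length(motif_chars) - 1L)] <<-
          motif_chars
      }
      starts
    }
    pp <- cfg$motif_plant_prob
    idx_cre <- which(bound$CREB & runif(n) < pp[["CREB"]])
    idx_cebp <- which(bound$CEBPB & runif(n) < pp[["CEBPB"]])
    idx_tre <- which(bound$CJUN & runif(n) < pp[["CJUN"]])
    st_cre <- plant(idx_cre, strsplit("TGACGTCA", "")[[1]], 501L, 653L)
    st_cebp <- plant(idx_cebp, strsplit("TTGCGCAA", "")[[1]], 671L, 813L)
    # TRE alternation: draw C or G per planted site
    st_tre <- integer(length(idx_tre))
    if (length(idx_tre)) {
      mid <- sample(c("C", "G"), length(idx_tre), replace = TRUE)
      for (ii in seq_along(idx_tre)) {
        chars <- strsplit(paste0("TGA", mid[ii], "TCA"), "")[[1]]
        st <- 831L + sample.int(984L - 831L + 1L, 1L) - 1L
        m[idx_tre[ii], st:(st + 6L)] <- chars
        st_tre[ii] <- st
      }
    }
    offset_cre[idx_cre] <- st_cre - 1001L
    offset_cebp[idx_cebp] <- st_cebp - 1001L
    offset_tre[idx_tre] <- st_tre - 1001L
    seqs <- do.call(paste0, as.data.frame(m))
    names(seqs) <- ids
  } else if (isTRUE(cfg$sequences)) {
    seqs <- setNames(character(0), character(0))
  }

  ## -- expression table ---------------------------------------------------
  fc_of <- function(status) {
    (cfg$expr_fc * ((status == "induced") - (status == "repressed"))) +
      rnorm(n, sd = cfg$expr_noise_sd)
  }
  expr_undiff <- rnorm(n, mean = 6, sd = 1.5)
  expr_diff <- expr_undiff + fc_of(mrna_status)
  acebp_hit <- bound$CEBPB & !bound$CREB & runif(n) < 0.6
  afos_hit <- bound$CJUN & !bound$CREB & runif(n) < 0.6
  aza_hit <- methylated & (bound$CEBPB | bound$CJUN) & !bound$CREB &
    runif(n) < 0.6
  expr <- data.table(
    row_id = if (n > 0) sprintf("r%06d", seq_len(n)) else character(0),
    genbank = if (n > 0) sprintf("NM_%06d", seq_len(n)) else character(0),
    symbol = if (n > 0) sprintf("Gene%05d", seq_len(n)) else character(0),
    unigene_cluster = if (n > 0) sprintf("Mm.%05d", seq_len(n))
                      else character(0),
    unigene_id = if (n > 0) sprintf("UG%06d", seq_len(n)) else character(0),
    expr_undiff = expr_undiff, expr_diff = expr_diff,
    expr_acebp = expr_diff - cfg$expr_fc * acebp_hit +
      rnorm(n, sd = cfg$expr_noise_sd),
    expr_afos = expr_diff - cfg$expr_fc * afos_hit +
      rnorm(n, sd = cfg$expr_noise_sd),
    expr_5aza = expr_diff - cfg$expr_fc * aza_hit +
      rnorm(n, sd = cfg$expr_noise_sd),
    expr_control = expr_diff + rnorm(n, sd = cfg$expr_noise_sd))
  # duplicate a fraction of rows (same identifiers, re-measured values)
  n_dup <- round(cfg$dup_row_frac * n)
  if (n_dup > 0) {
    di <- sort(sample.int(n, n_dup))
    extra <- copy(expr[di])
    extra[, row_id := sprintf("r%06db", di)]
    numcols <- grep("^expr_", names(extra), value = TRUE)
    for (cl in numcols) {
      extra[[cl]] <- extra[[cl]] + rnorm(n_dup, sd = 0.05)
    }
    expr <- rbind(expr, extra)
    setorder(expr, row_id)
  }
  truth <- data.table(
    promoter_id = ids, pattern = pattern,
    bound_CREB = bound$CREB, bound_CEBPB = bound$CEBPB,
    bound_CEBPA = bound$CEBPA, bound_CJUN = bound$CJUN,
    rnap_status = rnap_status, mrna_status = mrna_status,
    h3k9ac_status = h3k9ac_status, methylated = methylated,
    offset_CRE = offset_cre, offset_CEBP = offset_cebp,
    offset_TRE = offset_tre)

  list(bundle = list(catalog = catalog, sequences = seqs,
                     signals = signals, expression = expr,
                     annotations = annotations, config = cfg),
       truth = truth)
}

#' Write a synthetic bundle to plain-text files
#'
#' Layout: `promoters.bed` (BED6, TSS in the start field),
#' `annotations.tsv`, `sequences.fa`, `tracks/<FACTOR>_<cond>_rep<k>.bedGraph`,
#' `expression.tsv`, `truth.tsv` (when given) and `config.json`.
#'
#' @param bundle bundle list from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @param truth optional truth `data.table` to include.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  cat_ <- bundle$catalog
  bed <- data.table(chrom = cat_$chrom, start = cat_$tss,
                    end = cat_$tss + 1L, name = cat_$promoter_id,
                    score = 0L, strand = cat_$strand)
  fwrite(bed, file.path(dir, "promoters.bed"), sep = "\t",
         col.names = FALSE)
  fwrite(bundle$annotations, file.path(dir, "annotations.tsv"), sep = "\t")
  if (!is.null(bundle$sequences)) {
    ss <- Biostrings::DNAStringSet(bundle$sequences)
    Biostrings::writeXStringSet(ss, file.path(dir, "sequences.fa"),
                                width = 80L)
  }
  sig <- bundle$signals
  if (nrow(sig)) {
    keys <- unique(sig[, .(factor, condition, replicate)])
    for (i in seq_len(nrow(keys))) {
      tr <- sig[keys[i], on = .(factor, condition, replicate)]
      fn <- sprintf("%s_%s_rep%d.bedGraph", keys$factor[i],
                    keys$condition[i], keys$replicate[i])
      fwrite(tr[, .(chrom, pos, end = pos + 1L, value)],
             file.path(dir, "tracks", fn), sep = "\t", col.names = FALSE)
    }
  }
  fwrite(bundle$expression, file.path(dir, "expression.tsv"), sep = "\t")
  if (!is.null(truth)) {
    fwrite(truth, file.path(dir, "truth.tsv"), sep = "\t")
  }
  cfg <- bundle$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset bundle from a directory
#'
#' Inverse of [write_bundle()]; tolerates a missing `sequences.fa`,
#' `truth.tsv` or `config.json`.
#'
#' @param dir bundle directory.
#' @return bundle list (plus `truth` when present).
#' @export
read_bundle <- function(dir) {
  catalog <- read_promoters(file.path(dir, "promoters.bed"),
                            annotations = file.path(dir, "annotations.tsv"))
  seq_path <- file.path(dir, "sequences.fa")
  seqs <- if (file.exists(seq_path))
    read_promoter_sequences(seq_path, catalog) else NULL
  signals <- read_signal_tracks(file.path(dir, "tracks"))
  expr <- read_expression(file.path(dir, "expression.tsv"))
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) fread(truth_path) else NULL
  cfg_path <- file.path(dir, "config.json")
  cfg <- if (file.exists(cfg_path)) jsonlite::read_json(cfg_path,
                                                        simplifyVector = TRUE)
         else NULL
  list(catalog = catalog, sequences = seqs, signals = signals,
       expression = expr,
       annotations = fread(file.path(dir, "annotations.tsv")),
       config = cfg, truth = truth)
}
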