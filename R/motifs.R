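# IUPAC ambiguity sets (upper case); lower-case n/x spacers are accepted by
# the pattern compiler and mapped through this table.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' @param x character vector of sequences over ACGTN.
#' @return reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Compile a degenerate consensus motif
#'
#' Accepts IUPAC one-letter codes, lower-case `n` wildcards and the
#' `(X/Y)` alternation notation used for printed consensus motifs, e.g.
#' `"TGA(C/G)TCA"` (the TRE/AP-1 site) or the composite
#' `"ACTACAnnTCCCA"`.  Each position compiles to a non-empty subset of
#' {A,C,G,T}; a wildcard position matches any base but never an `N` in the
#' scanned sequence.
#'
#' @param text the pattern string.
#' @param name motif name (default the pattern text).
#' @return a `motif_pattern`: list with `name`, `text`, `length`, `sets`
#'   (per-position base sets).
#' @export
compile_pattern <- function(text, name = text) {
  chars <- strsplit(text, "")[[1]]
  sets <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      j <- i + 1L
      alt <- character(0)
      repeat {
        if (j > length(chars)) stop("unbalanced parentheses in motif: ", text)
        if (chars[j] == ")") break
        if (chars[j] != "/") alt <- c(alt, toupper(chars[j]))
        j <- j + 1L
      }
      bad <- setdiff(alt, names(IUPAC_SETS))
      if (length(bad) || !length(alt)) {
        stop("invalid letter in alternation of motif: ", text)
      }
      sets[[length(sets) + 1L]] <-
        sort(unique(unlist(IUPAC_SETS[alt], use.names = FALSE)))
      i <- j + 1L
    } else {
      up <- toupper(ch)
      if (!up %in% names(IUPAC_SETS)) {
        stop("invalid motif letter '", ch, "' in: ", text)
      }
      sets[[length(sets) + 1L]] <- IUPAC_SETS[[up]]
      i <- i + 1L
    }
  }
  if (!length(sets)) stop("empty motif pattern")
  structure(list(name = name, text = text, length = length(sets),
                 sets = sets),
            class = "motif_pattern")
}

# per-position membership of the reverse complement pattern
revcomp_sets <- function(sets) {
  lapply(rev(sets), function(s) sort(unname(COMPLEMENT[s])))
}

# logical lookup over base codes 1..4 (A,C,G,T) for each motif position
set_lookups <- function(sets) {
  lapply(sets, function(s) c("A", "C", "G", "T") %in% s)
}

# match start positions of a compiled set list in an integer code vector
# (A=1..T=4, NA for N); O(length * motif length)
match_codes <- function(codes, sets) {
  L <- length(codes)
  m <- length(sets)
  if (m > L) return(integer(0))
  npos <- L - m + 1L
  ok <- rep(TRUE, npos)
  lks <- set_lookups(sets)
  for (j in seq_len(m)) {
    v <- lks[[j]][codes[j:(j + npos - 1L)]]
    v[is.na(v)] <- FALSE
    ok <- ok & v
    if (!any(ok)) break
  }
  which(ok)
}

#' Scan one promoter sequence for a motif
#'
#' Scans the window (default -500..0 relative to the TSS) of a
#' promoter-strand sequence for the motif and its reverse complement.  A
#' hit must lie fully inside the window; `N` bases never match; when the
#' forward and reverse strands hit at the same offset (palindromic sites)
#' the hit is reported once, on the plus strand.
#'
#' @param seq one promoter sequence (character scalar, promoter-strand
#'   orientation; position 1 is relative position -1000).
#' @param motif a [compile_pattern()] result.
#' @param window integer length-2 vector `c(from, to)` of relative
#'   positions, half-open (default `c(-500, 0)`).
#' @param promoter_id id recorded in the output (default `""`).
#' @param tss_pos 1-based index of relative position 0 in `seq` (default
#'   1001, the -1000..+500 layout).
#' @return `data.table` with `promoter_id`, `motif`, `offset` (relative
#'   position of the first base; `offset + length <= 0`), `strand`.
#' @export
scan_promoter <- function(seq, motif, window = c(-500, 0),
                          promoter_id = "", tss_pos = 1001L) {
  stopifnot(inherits(motif, "motif_pattern"), length(window) == 2)
  s <- toupper(as.character(seq))
  if (length(s) != 1L) stop("scan_promoter takes a single sequence")
  L <- nchar(s)
  i1 <- window[1] + tss_pos
  i2 <- window[2] + tss_pos - 1L  # last included base
  if (i1 < 1L || i2 > L || i1 > i2) {
    stop("window outside the promoter region")
  }
  codes <- match(strsplit(substr(s, i1, i2), "")[[1]],
                 c("A", "C", "G", "T"))
  fwd <- match_codes(codes, motif$sets)
  rev_ <- match_codes(codes, revcomp_sets(motif$sets))
  off_f <- window[1] + fwd - 1L
  off_r <- window[1] + setdiff(rev_, fwd) - 1L
  out <- data.table(
    promoter_id = promoter_id, motif = motif$name,
    offset = c(off_f, off_r),
    strand = rep(c("+", "-"), c(length(off_f), length(off_r))))
  setorder(out, offset)
  out[]
}

#' Motif presence matrix over a promoter catalog
#'
#' Vectorised both-strand scan of each motif over the window of every
#' sequence; records presence/absence (the combination statistics are
#' driven by presence, not by site counts).
#'
#' @param seqs named character vector of promoter sequences (equal
#'   lengths).
#' @param motifs list of [compile_pattern()] results (or a single one).
#' @param window,tss_pos see [scan_promoter()].
#' @return logical matrix, promoters x motifs (dimnames set).
#' @export
motif_presence <- function(seqs, motifs, window = c(-500, 0),
                           tss_pos = 1001L) {
  if (inherits(motifs, "motif_pattern")) motifs <- list(motifs)
  names(motifs) <- vapply(motifs, `[[`, character(1), "name")
  nm <- names(seqs)
  seqs <- toupper(as.character(seqs))
  names(seqs) <- nm
  n <- length(seqs)
  if (n == 0L) {
    return(matrix(logical(0), 0, length(motifs),
                  dimnames = list(NULL, names(motifs))))
  }
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences must have equal length")
  }
  i1 <- window[1] + tss_pos
  i2 <- window[2] + tss_pos - 1L
  if (i1 < 1L || i2 > nchar(seqs[1]) || i1 > i2) {
    stop("window outside the promoter region")
  }
  W <- i2 - i1 + 1L
  codes <- matrix(match(unlist(strsplit(substr(seqs, i1, i2), ""),
                               use.names = FALSE),
                        c("A", "C", "G", "T")),
                  nrow = n, ncol = W, byrow = TRUE)
  out <- matrix(FALSE, n, length(motifs),
                dimnames = list(names(seqs), names(motifs)))
  for (mi in seq_along(motifs)) {
    mot <- motifs[[mi]]
    m <- mot$length
    if (m > W) next
    npos <- W - m + 1L
    present <- rep(FALSE, n)
    for (sets in list(mot$sets, revcomp_sets(mot$sets))) {
      lks <- set_lookups(sets)
      ok <- matrix(TRUE, n, npos)
      for (j in seq_len(m)) {
        v <- lks[[j]][codes[, j:(j + npos - 1L), drop = FALSE]]
        v[is.na(v)] <- FALSE
        ok <- ok & matrix(v, n, npos)
      }
      present <- present | (rowSums(ok) > 0L)
    }
    out[, mi] <- present
  }
  out
}

#' The printed consensus and composite motifs
#'
#' Loads the motif configuration shipped with the package: the CRE
#' (TGACGTCA), C/EBP (TTGCGCAA) and TRE/AP-1 (TGA(C/G)TCA) consensus
#' sites plus the composite motifs reported for the occupancy groups
#' (ZFP143-RBPJ `ACTACAnnTCCCA`, the C/EBP--AP-1 composites, and both
#' printed variants of the long C/EBP--c-Jun motif, which differ by one T
#' and are shipped unreconciled).
#'
#' @param path motif table (TSV: `name`, `pattern`); default the shipped
#'   configuration.
#' @return named list of `motif_pattern`s.
#' @export
default_motifs <- function(path = system.file("extdata", "motifs.tsv",
                                              package = "combichip")) {
  tab <- fread(path)
  stopifnot(all(c("name", "pattern") %in% names(tab)))
  mots <- lapply(seq_len(nrow(tab)), function(i)
    compile_pattern(tab$pattern[i], name = tab$name[i]))
  names(mots) <- tab$name
  mots
}

#' Enrichment of a motif combination in one occupancy group
#'
#' A promoter carries the combination when it contains every motif in
#' `combo`; with `exclusive = TRUE` (the "containing only" reading) it
#' must additionally lack every other motif in `motif_universe`.  The
#' group fraction is divided by the all-promoter fraction, with a
#' chi-square goodness-of-fit p-value of the observed split against the
#' background rate.
#'
#' @param presence logical promoters x motifs matrix
#'   ([motif_presence()]).
#' @param patterns output of [assign_patterns()] over the same universe.
#' @param combo character vector of motif names.
#' @param label occupancy-pattern label defining the group.
#' @param exclusive require absence of the other motifs (default TRUE).
#' @param motif_universe motifs considered for exclusivity (default the
#'   columns named in `combo` plus the other consensus motifs present in
#'   `presence`).
#' @return one-row `data.table`: `label`, `combo`, `n_group`,
#'   `n_with_combo`, `fraction`, `background_fraction`, `enrichment`, `p`.
#' @export
combo_enrichment <- function(presence, patterns, combo, label,
                             exclusive = TRUE,
                             motif_universe = colnames(presence)) {
  stopifnot(all(combo %in% colnames(presence)))
  has <- rowSums(presence[, combo, drop = FALSE]) == length(combo)
  if (exclusive) {
    others <- setdiff(intersect(motif_universe, colnames(presence)), combo)
    if (length(others)) {
      has <- has & rowSums(presence[, others, drop = FALSE]) == 0L
    }
  }
  ids_all <- intersect(rownames(presence), patterns$promoter_id)
  has <- has[ids_all]
  lab <- label
  grp_ids <- intersect(patterns$promoter_id[patterns$label == lab], ids_all)
  n_all <- length(ids_all)
  bg <- sum(has) / n_all
  ng <- length(grp_ids)
  nw <- sum(has[grp_ids])
  frac <- if (ng > 0) nw / ng else NA_real_
  enr <- if (ng > 0 && bg > 0) frac / bg else NA_real_
  p <- if (ng > 0 && bg > 0 && bg < 1) {
    chi_square_gof(c(nw, ng - nw), c(bg * ng, (1 - bg) * ng))$p
  } else NA_real_
  data.table(label = lab, combo = paste(combo, collapse = "+"),
             n_group = ng, n_with_combo = nw, fraction = frac,
             background_fraction = bg, enrichment = enr, p = p)
}

#' Motif-combination enrichment across all occupancy groups
#'
#' Computes [combo_enrichment()] for every pattern label and every
#' combination of two or three of the consensus motifs.
#'
#' @param presence logical promoters x motifs matrix.
#' @param patterns output of [assign_patterns()].
#' @param consensus the three consensus motif names
#'   (default `c("CRE", "CEBP", "TRE")`).
#' @param exclusive see [combo_enrichment()].
#' @return `data.table`, one row per label x combination.
#' @export
combo_enrichment_table <- function(presence, patterns,
                                   consensus = c("CRE", "CEBP", "TRE"),
                                   exclusive = TRUE) {
  labs <- pattern_labels(attr(patterns, "factors"))
  combos <- c(utils::combn(consensus, 2, simplify = FALSE),
              list(consensus))
  rbindlist(lapply(labs, function(l)
    rbindlist(lapply(combos, function(cb)
      combo_enrichment(presence, patterns, cb, l, exclusive = exclusive,
                       motif_universe = consensus)))))[]
}

#' Colocalization ratio of a motif pair in an occupancy group
#'
#' The rate of promoters carrying both motifs inside the group, normalised
#' to the rate over all promoters.
#'
#' @param presence logical promoters x motifs matrix.
#' @param pair two motif names.
#' @param group_ids promoter ids of the group.
#' @param universe_ids promoter ids of the universe (default all rows).
#' @return the ratio (group rate / universe rate).
#' @export
colocalization_ratio <- function(presence, pair, group_ids,
                                 universe_ids = rownames(presence)) {
  stopifnot(length(pair) == 2, all(pair %in% colnames(presence)))
  if (!length(group_ids) || !length(universe_ids)) {
    stop("empty group or universe")
  }
  co <- rowSums(presence[, pair, drop = FALSE]) == 2L
  uni_rate <- sum(co[universe_ids]) / length(universe_ids)
  if (uni_rate == 0) stop("no co-occurrence in the universe")
  grp_rate <- sum(co[group_ids]) / length(group_ids)
  grp_rate / uni_rate
}
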