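#' Read promoter definitions from a BED6 file
#'
#' Each BED record anchors one promoter at its transcription start site
#' (TSS): the TSS is the `start` field of the record and the analysis region
#' is derived as -1000..+500 relative to the TSS *on the promoter strand*
#' (0-based, half-open).  For a plus-strand promoter with TSS `t` the region
#' is `[t-1000, t+500)`; for a minus-strand promoter a relative position `r`
#' maps to genomic `t - r`, giving `[t-499, t+1001)`.  Both regions are
#' 1500 bp.
#'
#' @param path path to a BED file with >= 6 tab- or space-separated columns
#'   (chrom, start, end, name, score, strand).  The `name` column is the
#'   promoter identifier and must be unique.
#' @param annotations optional path to (or data.frame of) a promoter
#'   annotation table with a `promoter_id` column; all remaining columns are
#'   treated as gene identifiers (GenBank accession, gene symbol, UniGene
#'   cluster/ID, ...) and collected into the `gene_ids` list column.
#' @return a `promoter_catalog` (a `data.table`) with columns
#'   `promoter_id`, `chrom`, `strand`, `tss`, `region_start`, `region_end`
#'   and `gene_ids` (list of character).
#' @export
read_promoters <- function(path, annotations = NULL) {
  if (!file.exists(path)) stop("promoter BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6)) {
    bad <- lineno[which(nf < 6)[1]]
    stop("malformed BED line ", bad, ": expected >= 6 columns")
  }
  m <- t(vapply(fields, function(f) f[1:6], character(6)))
  start <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(start)) {
    bad <- lineno[which(is.na(start))[1]]
    stop("malformed BED line ", bad, ": non-integer start coordinate")
  }
  strand <- m[, 6]
  strand[strand == "−"] <- "-"  # tolerate unicode minus
  if (!all(strand %in% c("+", "-"))) {
    bad <- lineno[which(!strand %in% c("+", "-"))[1]]
    stop("malformed BED line ", bad, ": missing or invalid strand")
  }
  dt <- data.table(
    promoter_id = m[, 4], chrom = m[, 1], strand = strand, tss = start
  )
  new_promoter_catalog(dt, annotations = annotations)
}

#' Construct a promoter catalog from a TSS table
#'
#' Internal constructor shared by [read_promoters()] and the synthetic
#' generator.  Derives the strand-aware -1000..+500 region and attaches gene
#' identifiers.
#'
#' @param dt data.table with `promoter_id`, `chrom`, `strand`, `tss`.
#' @param annotations see [read_promoters()].
#' @return a `promoter_catalog`.
#' @keywords internal
new_promoter_catalog <- function(dt, annotations = NULL) {
  dt <- as.data.table(dt)
  if (anyDuplicated(dt$promoter_id)) {
    d <- unique(dt$promoter_id[duplicated(dt$promoter_id)])
    stop("duplicate promoter_id(s): ", paste(head(d, 5), collapse = ", "))
  }
  if (!all(dt$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  dt[, region_start := ifelse(strand == "+", tss - 1000L, tss - 499L)]
  dt[, region_end := region_start + 1500L]
  dt[, gene_ids := as.list(promoter_id)]
  if (!is.null(annotations)) {
    ann <- if (is.character(annotations)) fread(annotations) else
      as.data.table(annotations)
    if (!"promoter_id" %in% names(ann)) {
      stop("annotation table must have a promoter_id column")
    }
    idcols <- setdiff(names(ann), "promoter_id")
    gl <- lapply(seq_len(nrow(ann)), function(i) {
      v <- unlist(ann[i, ..idcols], use.names = FALSE)
      unique(v[!is.na(v) & nzchar(v)])
    })
    names(gl) <- ann$promoter_id
    hit <- dt$promoter_id %in% names(gl)
    dt$gene_ids[hit] <- gl[dt$promoter_id[hit]]
  }
  setattr(dt, "class", c("promoter_catalog", class(dt)))
  dt[]
}

#' Read promoter sequences from FASTA
#'
#' Sequences are keyed by promoter identifier and stored in promoter-strand
#' orientation (the first base is relative position -1000, the last is
#' +499).  The alphabet is restricted to A, C, G, T and N.
#'
#' @param path FASTA file.
#' @param catalog optional `promoter_catalog`; if given, every catalog
#'   promoter must have a sequence of the region length.
#' @return named character vector of upper-case sequences.
#' @export
read_promoter_sequences <- function(path, catalog = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("sequence with letters outside ACGTN: ",
         paste(head(names(seqs)[bad], 3), collapse = ", "))
  }
  if (!is.null(catalog)) {
    miss <- setdiff(catalog$promoter_id, names(seqs))
    if (length(miss)) {
      stop("promoter(s) lacking a sequence: ",
           paste(head(miss, 5), collapse = ", "))
    }
    len <- catalog$region_end - catalog$region_start
    sl <- nchar(seqs[catalog$promoter_id])
    if (any(sl != len)) {
      stop("sequence length != region length for: ",
           paste(head(catalog$promoter_id[sl != len], 5), collapse = ", "))
    }
  }
  seqs
}

#' Length of the longest run of unsequenced (N) bases
#'
#' @param seq a single sequence, or a (named) character vector of sequences.
#' @return integer vector of the longest maximal N-run per sequence
#'   (0 if none).
#' @export
longest_unsequenced_run <- function(seq) {
  seq <- as.character(seq)
  if (length(seq) == 0L) return(integer(0))
  if (any(!nzchar(seq))) stop("empty sequence")
  vapply(seq, function(s) {
    m <- gregexpr("N+", s)[[1]]
    if (m[1] == -1L) 0L else max(attr(m, "match.length"))
  }, integer(1), USE.NAMES = !is.null(names(seq)))
}

#' Promoters sharing an exact window of sequence with many others
#'
#' Flags promoters that contain any length-`window` substring (on either
#' strand) that also occurs, on either strand, in at least `min_other`
#' *other* promoters.  Matching is exact; windows containing N are ignored
#' (unsequenced stretches are handled by the N-run filter).  The result is
#' deterministic and independent of input order.
#'
#' @param seqs named character vector of promoter sequences.
#' @param window window length in bp (default 150).
#' @param min_other minimum number of *other* promoters sharing the window
#'   (default 10).
#' @return character vector of flagged promoter ids (sorted).
#' @export
duplicated_window_index <- function(seqs, window = 150L, min_other = 10L) {
  if (window < 1L) stop("window must be >= 1")
  nm <- names(seqs)
  seqs <- toupper(as.character(seqs))  # toupper drops names
  names(seqs) <- nm
  if (length(seqs) == 0L) return(character(0))
  if (is.null(names(seqs))) names(seqs) <- as.character(seq_along(seqs))
  if (any(nchar(seqs) < window)) {
    stop("window longer than at least one sequence")
  }
  flagged <- dup_window_flags(seqs, as.integer(window), as.integer(min_other))
  sort(names(seqs)[flagged])
}

#' Apply the promoter exclusion rules
#'
#' Removes from the catalog (1) promoters on the sex chromosomes, (2)
#' promoters whose sequence contains an unsequenced (N) run strictly longer
#' than `max_n_run` bp, and (3) promoters carrying an exact `window`-bp
#' stretch of sequence shared with `min_other` or more other promoters.
#' The exclusion sets may overlap; each promoter is removed once.
#'
#' @param catalog a `promoter_catalog`.
#' @param seqs named character vector of promoter sequences covering every
#'   catalog promoter.
#' @param max_n_run longest tolerated N run (strictly greater is excluded).
#' @param window,min_other see [duplicated_window_index()].
#' @return list with `catalog` (retained subset, still a
#'   `promoter_catalog`) and `report`, a filter report list with fields
#'   `n_input`, `n_excluded_sex`, `n_excluded_unsequenced`,
#'   `n_excluded_duplicated`, `n_retained` and `excluded_ids` (per-rule id
#'   sets).
#' @export
apply_promoter_filters <- function(catalog, seqs, max_n_run = 150L,
                                   window = 150L, min_other = 10L) {
  nm <- names(seqs)
  seqs <- toupper(as.character(seqs))
  names(seqs) <- nm
  miss <- setdiff(catalog$promoter_id, names(seqs))
  if (length(miss)) {
    stop("promoter(s) lacking a sequence: ",
         paste(head(miss, 5), collapse = ", "))
  }
  seqs <- seqs[catalog$promoter_id]
  sex <- tolower(catalog$chrom) %in% c("chrx", "chry", "x", "y")
  sex_ids <- catalog$promoter_id[sex]
  if (length(seqs)) {
    nrun <- longest_unsequenced_run(seqs)
    unseq_ids <- catalog$promoter_id[nrun > max_n_run]
    dup_ids <- duplicated_window_index(seqs, window = window,
                                       min_other = min_other)
  } else {
    unseq_ids <- character(0)
    dup_ids <- character(0)
  }
  excl <- union(sex_ids, union(unseq_ids, dup_ids))
  keep <- !(catalog$promoter_id %in% excl)
  retained <- catalog[keep]
  setattr(retained, "class", class(catalog))
  report <- list(
    n_input = nrow(catalog),
    n_excluded_sex = length(sex_ids),
    n_excluded_unsequenced = length(unseq_ids),
    n_excluded_duplicated = length(dup_ids),
    n_retained = nrow(retained),
    excluded_ids = list(
      sex = sort(sex_ids),
      unsequenced = sort(unseq_ids),
      duplicated = sort(dup_ids)
    )
  )
  list(catalog = retained[], report = report)
}
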