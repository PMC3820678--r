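#' Read a gene-expression summary table
#'
#' Expected columns: `row_id`, identifier columns (`genbank`, `symbol`,
#' `unigene_cluster`, `unigene_id`; missing ones are tolerated),
#' `expr_undiff`, `expr_diff` (log2 expression) and optional perturbation
#' columns (`expr_acebp`, `expr_afos`, `expr_5aza`, `expr_control`).
#'
#' @param path TSV file with a header.
#' @return `data.table` of expression records.
#' @export
read_expression <- function(path) {
  dt <- fread(path)
  need <- c("row_id", "expr_undiff", "expr_diff")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("expression table lacks column(s): ",
                         paste(miss, collapse = ", "))
  idcols <- intersect(c("genbank", "symbol", "unigene_cluster", "unigene_id"),
                      names(dt))
  if (!length(idcols)) stop("expression table has no identifier columns")
  dt
}

#' Map expression rows onto promoters via shared gene identifiers
#'
#' A row and a promoter match when they share any identifier (GenBank
#' accession, gene symbol, UniGene cluster or UniGene ID; matching is exact
#' but case-insensitive).  All matches are kept: a row matching two
#' promoters contributes to both, and when several rows map to one
#' promoter their values are averaged.
#'
#' @param expr expression `data.table` (see [read_expression()]).
#' @param catalog a `promoter_catalog` whose `gene_ids` carry the same
#'   identifier vocabulary.
#' @return `data.table` with `promoter_id`, `log2fc` (diff - undiff,
#'   averaged over contributing rows), one `log2fc_<pert>` column per
#'   perturbation column present (value relative to `expr_diff`), and
#'   `n_source_rows`.  Promoters with no matching row are absent.
#' @export
map_expression <- function(expr, catalog) {
  expr <- as.data.table(expr)
  idcols <- intersect(c("genbank", "symbol", "unigene_cluster", "unigene_id"),
                      names(expr))
  # long identifier -> row map
  long <- rbindlist(lapply(idcols, function(cl) {
    data.table(identifier = tolower(as.character(expr[[cl]])),
               row = seq_len(nrow(expr)))
  }))
  long <- long[!is.na(identifier) & nzchar(identifier)]
  long <- unique(long)
  # promoter -> identifier map
  pmap <- catalog[, .(identifier = tolower(unlist(gene_ids))),
                  by = promoter_id]
  pmap <- pmap[!is.na(identifier) & nzchar(identifier)]
  matched <- merge(pmap, long, by = "identifier", allow.cartesian = TRUE)
  if (!nrow(matched)) {
    return(data.table(promoter_id = character(0), log2fc = numeric(0),
                      n_source_rows = integer(0)))
  }
  pairs <- unique(matched[, .(promoter_id, row)])
  vals <- data.table(row = seq_len(nrow(expr)),
                     log2fc = expr$expr_diff - expr$expr_undiff)
  perts <- intersect(c("expr_acebp", "expr_afos", "expr_5aza"), names(expr))
  for (p in perts) {
    vals[[paste0("log2fc_", sub("^expr_", "", p))]] <-
      expr[[p]] - expr$expr_diff
  }
  joined <- merge(pairs, vals, by = "row")
  valcols <- setdiff(names(vals), "row")
  out <- joined[, c(lapply(.SD, mean), list(n_source_rows = .N)),
                by = promoter_id, .SDcols = valcols]
  setorder(out, promoter_id)
  out[]
}

#' mRNA change call upon differentiation
#'
#' Induced when the log2 fold change strictly exceeds the threshold,
#' repressed when it is strictly below its negative, unchanged otherwise.
#' The default 0.5 on the log2 scale corresponds to a 1.4-fold change.
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @param cfg a [threshold_config()] (uses `cfg$mrna_log2fc`), or a single
#'   numeric threshold.
#' @return character vector of statuses (`NA` propagated).
#' @export
call_mrna_change <- function(log2fc, cfg = threshold_config()) {
  thr <- if (is.numeric(cfg)) cfg else cfg$mrna_log2fc
  status <- rep(NA_character_, length(log2fc))
  ok <- !is.na(log2fc)
  status[ok] <- "unchanged"
  status[ok & log2fc > thr] <- "induced"
  status[ok & log2fc < -thr] <- "repressed"
  status
}
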