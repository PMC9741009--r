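#' Mutation frequency in bp per event
#'
#' Density of accepted mutations expressed as genome size divided by the
#' number of events, reported to 2 decimals. Smaller values mean denser
#' mutation loads. Undefined (NA) when `n_events` is zero.
#'
#' @param genome_size genome size, bp (default 430 Mbp, the rice genome
#'   size conventionally used for this statistic)
#' @param n_events number of accepted mutations
#' @return bp/event, rounded to 2 decimals; NA when `n_events` = 0
#' @export
mutation_frequency <- function(genome_size = 430e6, n_events) {
  stopifnot(genome_size >= 1, all(n_events >= 0))
  ifelse(n_events > 0, round(genome_size / n_events, 2), NA_real_)
}

#' Derive spectrum columns from per-line counts
#'
#' Computes the derived columns of a mutation-spectrum table from its raw
#' count columns: reported deletion count (translocations are also
#' recorded as deletions from their origin locus, so `del_reported = del +
#' itx + ctx` when the convention is on), SV total (`del_reported + dup +
#' inv + ins`), small total (`snv + indel`), grand total, bp/event
#' frequencies and the SV share of all mutations.
#'
#' @param counts data.frame with columns `snv`, `indel`, `del`, `dup`,
#'   `inv`, `ins`, `itx`, `ctx` (one row per line; extra columns carried
#'   through)
#' @param genome_size bp, for the frequency columns
#' @param count_translocations_as_deletions apply the origin-locus
#'   deletion convention (default TRUE); set FALSE if the `del` column
#'   already includes translocation-origin deletions
#' @return `counts` plus `del_reported`, `n_sv`, `n_small`, `n_total`,
#'   `freq_small`, `freq_all`, `freq_sv`, `sv_share`
#' @export
derive_spectrum <- function(counts, genome_size = 430e6,
                            count_translocations_as_deletions = TRUE) {
  need <- c("snv", "indel", "del", "dup", "inv", "ins", "itx", "ctx")
  stopifnot(all(need %in% names(counts)))
  counts$del_reported <- counts$del +
    if (count_translocations_as_deletions) counts$itx + counts$ctx else 0L
  counts$n_sv <- counts$del_reported + counts$dup + counts$inv + counts$ins
  counts$n_small <- counts$snv + counts$indel
  counts$n_total <- counts$n_small + counts$n_sv
  counts$freq_small <- mutation_frequency(genome_size, counts$n_small)
  counts$freq_all <- mutation_frequency(genome_size, counts$n_total)
  counts$freq_sv <- mutation_frequency(genome_size, counts$n_sv)
  counts$sv_share <- ifelse(counts$n_total > 0,
                            round(100 * counts$n_sv / counts$n_total, 2), NA_real_)
  counts
}

#' Build the per-line mutation spectrum and density report
#'
#' Combines the accepted small-variant catalog and consensus SV records
#' into one row per mutant line: counts per class, bp/event frequencies
#' over `genome_size`, and the SV share of all mutations. Translocations
#' are also recorded as deletions from their origin locus before totals
#' (toggleable). An `ALL` aggregate row sums the count columns, and an SV
#' composition table gives each type's share of the SV total.
#'
#' @param catalog a `radmut_catalog` from [run_cascade()]
#' @param sv_records consensus SV records from [sv_consensus()] (the
#'   `records` element), or NULL for a small-variant-only report
#' @param manifest sample manifest (for treatment/dose columns)
#' @param genome_size bp; use the simulated genome size for synthetic runs
#' @param count_translocations_as_deletions see [derive_spectrum()]
#' @return a `radmut_report` list: `per_line` (data.frame), `aggregate`
#'   (one row), `sv_composition` (counts and percent of SV total per type)
#' @export
build_report <- function(catalog, sv_records = NULL, manifest = NULL,
                         genome_size = 430e6,
                         count_translocations_as_deletions = TRUE) {
  lines <- catalog$lines
  sv_records <- sv_records %||% data.frame(line_id = character(),
                                           sv_type = character())
  count_type <- function(l, t) sum(sv_records$line_id == l &
                                   sv_records$sv_type == t)
  rows <- lapply(lines, function(l) {
    acc <- catalog$accepted[catalog$accepted$line_id == l, ]
    data.frame(line_id = l,
               snv = sum(acc$class == "snv"),
               indel = sum(acc$class == "indel"),
               del = count_type(l, "DEL"), dup = count_type(l, "DUP"),
               inv = count_type(l, "INV"), ins = count_type(l, "INS"),
               itx = count_type(l, "ITX"), ctx = count_type(l, "CTX"),
               stringsAsFactors = FALSE)
  })
  per_line <- derive_spectrum(do.call(rbind, rows), genome_size,
                              count_translocations_as_deletions)
  if (!is.null(manifest)) {
    m <- manifest[!duplicated(manifest$line_id), ]
    per_line$treatment <- m$treatment[match(per_line$line_id, m$line_id)]
    per_line$dose_gy <- m$dose_gy[match(per_line$line_id, m$line_id)]
  }
  count_cols <- c("snv", "indel", "del", "dup", "inv", "ins", "itx", "ctx")
  agg_counts <- as.data.frame(as.list(colSums(per_line[, count_cols])))
  agg_counts$line_id <- "ALL"
  aggregate_row <- derive_spectrum(agg_counts, genome_size,
                                   count_translocations_as_deletions)
  comp_counts <- c(DEL = sum(per_line$del_reported), DUP = sum(per_line$dup),
                   INV = sum(per_line$inv), INS = sum(per_line$ins),
                   ITX = sum(per_line$itx), CTX = sum(per_line$ctx))
  sv_total <- aggregate_row$n_sv
  sv_composition <- data.frame(
    sv_type = names(comp_counts), count = as.integer(comp_counts),
    pct_of_sv_total = if (sv_total > 0)
      round(100 * as.numeric(comp_counts) / sv_total, 2) else NA_real_,
    stringsAsFactors = FALSE)
  structure(list(per_line = per_line, aggregate = aggregate_row,
                 sv_composition = sv_composition,
                 genome_size = genome_size),
            class = "radmut_report")
}

#' Write a spectrum report as TSV and JSON
#'
#' @param report a `radmut_report`
#' @param tsv,json output paths (either may be NULL to skip)
#' @return invisibly, the paths written
#' @export
write_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    write.table(report$per_line, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json)) {
    summary <- list(
      genome_size = report$genome_size,
      n_lines = nrow(report$per_line),
      per_line = report$per_line,
      aggregate = report$aggregate,
      sv_composition = report$sv_composition,
      sv_share_range = range(report$per_line$sv_share, na.rm = TRUE),
      freq_small_range = range(report$per_line$freq_small, na.rm = TRUE))
    jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(list(tsv = tsv, json = json))
}
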