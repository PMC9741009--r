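#' Configuration of the structural-variant pipeline
#'
#' Defaults follow a multi-caller SV analysis of 30x short-read data from
#' a mutagenized population: translocations require strictly more than 100
#' supporting reads; other SV types require a caller-specific minimum
#' (50 read pairs for a BreakDancer-like caller; 50, alternatively 10, for
#' a Lumpy-like caller); records are merged when both breakpoints agree
#' within +/- 2000 bp. The 2000 bp tolerance is stated for translocation
#' merging and is applied here to all SV types for cross-caller and
#' cross-line matching, there being no separate tolerance for other types.
#'
#' @param translocation_min_support minimum reads for ITX/CTX, strict
#'   greater-than (default 100)
#' @param default_min_support minimum reads for non-translocation SVs,
#'   inclusive (default 50)
#' @param caller_min_support optional named vector of per-caller overrides
#'   for non-translocation SVs (e.g. `c(lumpy = 10)`)
#' @param merge_tolerance breakpoint matching tolerance, bp (default 2000)
#' @param min_callers minimum distinct callers supporting a consensus
#'   record (default 1; the source analysis states no cross-caller
#'   consensus requirement)
#' @param require_both_replicates require presence in both replicates
#'   (default TRUE)
#' @param cross_line_filter `"strict"` removes records matching another
#'   line or a control; `"report_only"` keeps them flagged `shared = TRUE`
#'   (large validated deletions can legitimately recur across lines)
#' @param bin_sizes depth-scan bin sizes, bp
#' @param del_depth_ratio_max mutant/control depth ratio at or below which
#'   a bin run is a deletion candidate (default 0.25)
#' @param dup_depth_ratio_min ratio at or above which a run is a
#'   duplication candidate (default 1.75)
#' @param depth_epsilon pseudodepth added to numerator and denominator
#' @return a `radmut_sv_config` list
#' @export
sv_config <- function(translocation_min_support = 100L,
                      default_min_support = 50L,
                      caller_min_support = NULL,
                      merge_tolerance = 2000L, min_callers = 1L,
                      require_both_replicates = TRUE,
                      cross_line_filter = c("strict", "report_only"),
                      bin_sizes = c(1000L, 5000L, 10000L, 100000L),
                      del_depth_ratio_max = 0.25,
                      dup_depth_ratio_min = 1.75,
                      depth_epsilon = 0.5) {
  stopifnot(merge_tolerance >= 0, translocation_min_support >= 1,
            default_min_support >= 1, min_callers >= 1,
            del_depth_ratio_max > 0, dup_depth_ratio_min > 1)
  structure(list(translocation_min_support = as.integer(translocation_min_support),
                 default_min_support = as.integer(default_min_support),
                 caller_min_support = caller_min_support,
                 merge_tolerance = as.integer(merge_tolerance),
                 min_callers = as.integer(min_callers),
                 require_both_replicates = isTRUE(require_both_replicates),
                 cross_line_filter = match.arg(cross_line_filter),
                 bin_sizes = as.integer(bin_sizes),
                 del_depth_ratio_max = del_depth_ratio_max,
                 dup_depth_ratio_min = dup_depth_ratio_min,
                 depth_epsilon = depth_epsilon),
            class = "radmut_sv_config")
}

#' Filter SV calls by supporting-read count
#'
#' Translocations (ITX/CTX) are kept only when supported by strictly more
#' than `translocation_min_support` reads. Other types must meet the
#' caller's minimum support (inclusive), `default_min_support` unless
#' overridden per caller in `caller_min_support`.
#'
#' @param svs SV calls data.frame with `sv_type`, `support`, `caller_id`
#' @param cfg an [sv_config()]
#' @return the retained rows
#' @export
support_filter <- function(svs, cfg = sv_config()) {
  if (!nrow(svs)) return(svs)
  stopifnot(all(c("sv_type", "support") %in% names(svs)))
  is_tx <- svs$sv_type %in% c("ITX", "CTX")
  min_other <- rep(cfg$default_min_support, nrow(svs))
  if (!is.null(cfg$caller_min_support) && "caller_id" %in% names(svs)) {
    hit <- match(svs$caller_id, names(cfg$caller_min_support))
    min_other[!is.na(hit)] <- cfg$caller_min_support[hit[!is.na(hit)]]
  }
  keep <- ifelse(is_tx, svs$support > cfg$translocation_min_support,
                 svs$support >= min_other)
  svs[keep, , drop = FALSE]
}

# union-find for single-linkage clustering
uf_find <- function(parent, i) {
  while (parent[i] != i) { parent[i] <- parent[parent[i]]; i <- parent[i] }
  i
}

# single-linkage clusters: records link iff same (type, chrom[, chrom2]) and
# both breakpoint deltas are within tolerance; returns integer cluster ids
sv_cluster_ids <- function(svs, tolerance) {
  n <- nrow(svs)
  if (n == 0) return(integer(0))
  grp <- paste(svs$sv_type, svs$chrom,
               ifelse(is.na(svs$chrom2), "", svs$chrom2))
  b2 <- ifelse(svs$sv_type == "CTX", svs$pos2, svs$end)
  parent <- seq_len(n)
  ord <- order(grp, svs$start)
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    for (b in (a + 1L):n) {
      j <- ord[b]
      if (grp[j] != grp[i]) break
      if (svs$start[j] - svs$start[i] > tolerance) break  # sorted by start
      if (abs(b2[i] - b2[j]) <= tolerance) {
        ri <- uf_find(parent, i); rj <- uf_find(parent, j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  match(roots, unique(roots))
}

# collapse one cluster into a consensus record: support-weighted mean
# coordinates (rounded), support = max, provenance aggregated
collapse_cluster <- function(rows) {
  w <- rows$support / sum(rows$support)
  s <- as.integer(round(sum(w * rows$start)))
  is_ctx <- rows$sv_type[1] == "CTX"
  e <- if (is_ctx) s else as.integer(round(sum(w * rows$end)))
  p2 <- if (is_ctx) as.integer(round(sum(w * rows$pos2))) else NA_integer_
  data.frame(
    sv_type = rows$sv_type[1], chrom = rows$chrom[1],
    start = s, end = max(s, e),
    chrom2 = rows$chrom2[1], pos2 = p2,
    size = if (is_ctx) NA_integer_ else
      if (rows$sv_type[1] == "INS") as.integer(round(mean(rows$size)))
      else as.integer(max(s, e) - s + 1L),
    support = max(rows$support),
    n_callers = length(unique(rows$caller_id)),
    n_replicates = length(unique(rows$sample_id)),
    callers = paste(sort(unique(rows$caller_id)), collapse = ","),
    n_records = nrow(rows), stringsAsFactors = FALSE)
}

#' Merge overlapping translocation calls within a line
#'
#' Single-linkage clustering of translocation records: two records are
#' linked when they share the chromosome (pair) and both the start and the
#' second breakpoint agree within `merge_tolerance` (+/- 2000 bp by
#' default). Each cluster collapses to one record with support-weighted
#' mean coordinates and the maximum support. Input must be translocations
#' of a single type (all ITX or all CTX).
#'
#' @param svs SV calls, all of one translocation type
#' @param cfg an [sv_config()]
#' @return merged records
#' @export
merge_translocations <- function(svs, cfg = sv_config()) {
  if (!nrow(svs)) return(svs)
  if (length(unique(svs$sv_type)) > 1L)
    stop("merge_translocations expects records of a single sv_type")
  if (!svs$sv_type[1] %in% c("ITX", "CTX"))
    stop("merge_translocations expects ITX or CTX records")
  cid <- sv_cluster_ids(svs, cfg$merge_tolerance)
  out <- do.call(rbind, lapply(split(svs, cid), collapse_cluster))
  rownames(out) <- NULL
  out[order(out$chrom, out$start), ]
}

#' Consolidate SV calls into per-line consensus records
#'
#' Within each line, support-filtered records of the same type are merged
#' across callers and replicates by single-linkage clustering at
#' `merge_tolerance`. A consensus record is kept when reported by at least
#' `min_callers` distinct callers and (by default) present in both
#' replicates. Records matching — same type, both breakpoints within
#' tolerance — a consensus record of another line or of a control are
#' natural-variation candidates: removed under `cross_line_filter =
#' "strict"`, retained with `shared = TRUE` under `"report_only"`.
#'
#' @param svs SV calls data.frame (per caller, per sample) with `line_id`,
#'   `sample_id`, `caller_id`, `sv_type`, coordinates, `support`
#' @param manifest sample manifest (`sample_id`, `line_id`, `role`)
#' @param cfg an [sv_config()]
#' @return a `radmut_sv_consensus` list: `records` (per-line consensus
#'   data.frame with `shared` flag), `removed` (records dropped and why)
#' @export
sv_consensus <- function(svs, manifest, cfg = sv_config()) {
  svs <- support_filter(svs, cfg)
  mut_lines <- unique(manifest$line_id[manifest$role == "mutant_rep"])
  ctl_lines <- setdiff(unique(manifest$line_id), mut_lines)
  per_line <- list()
  for (l in unique(svs$line_id)) {
    sub <- svs[svs$line_id == l, ]
    cid <- sv_cluster_ids(sub, cfg$merge_tolerance)
    cons <- do.call(rbind, lapply(split(sub, cid), collapse_cluster))
    cons$line_id <- l
    reps <- manifest$sample_id[manifest$line_id == l]
    cons$both_replicates <- cons$n_replicates >= min(2L, length(reps))
    per_line[[l]] <- cons
  }
  all_cons <- do.call(rbind, c(per_line, list(NULL)))
  if (is.null(all_cons))
    return(structure(list(records = data.frame(), removed = data.frame()),
                     class = "radmut_sv_consensus"))
  rownames(all_cons) <- NULL
  keep <- all_cons$n_callers >= cfg$min_callers &
    (!cfg$require_both_replicates | all_cons$both_replicates)
  removed <- all_cons[!keep, , drop = FALSE]
  removed$shared <- rep(NA, nrow(removed))
  removed$removed_reason <- if (nrow(removed))
    ifelse(removed$n_callers < cfg$min_callers,
           "insufficient_callers", "replicate_discordant") else character(0)
  cons <- all_cons[keep, , drop = FALSE]

  # cross-line / control matching on the consensus records
  cons$shared <- FALSE
  if (nrow(cons) > 1L) {
    cid <- sv_cluster_ids(cons, cfg$merge_tolerance)
    lines_per <- tapply(cons$line_id, cid, function(x) unique(x))
    for (cl in names(lines_per)) {
      ln <- lines_per[[cl]]
      if (length(ln) > 1L || any(ln %in% ctl_lines))
        cons$shared[cid == as.integer(cl)] <- TRUE
    }
  }
  cons$shared <- cons$shared | cons$line_id %in% ctl_lines
  if (cfg$cross_line_filter == "strict") {
    nat <- cons[cons$shared, , drop = FALSE]
    if (nrow(nat)) {
      nat$removed_reason <- "shared_across_lines_or_control"
      removed <- rbind(removed, nat[, names(removed), drop = FALSE])
    }
    cons <- cons[!cons$shared, , drop = FALSE]
  } else {
    cons <- cons[!cons$line_id %in% ctl_lines, , drop = FALSE]
  }
  rownames(cons) <- NULL
  structure(list(records = cons, removed = removed),
            class = "radmut_sv_consensus")
}

#' Scan read-depth bins for large deletions and duplications
#'
#' Per bin, computes ratio = (mutant + eps) / (control + eps) on equal-size
#' bin tracks normalized to the same library size. Maximal runs of bins
#' with ratio <= `del_depth_ratio_max` become deletion candidates; runs
#' with ratio >= `dup_depth_ratio_min` become duplication candidates.
#' Candidate coordinates span the run extent.
#'
#' @param mutant_bins,control_bins data.frames (`chrom`, `bin_start`,
#'   `depth`) with identical bin structure
#' @param bin_size bin width, bp
#' @param cfg an [sv_config()]
#' @return data.frame of candidates: `sv_type` (DEL/DUP), `chrom`,
#'   `start`, `end`, `size`, `n_bins`, `mean_ratio`
#' @export
bin_depth_scan <- function(mutant_bins, control_bins, bin_size,
                           cfg = sv_config()) {
  if (nrow(mutant_bins) != nrow(control_bins) ||
      !all(mutant_bins$chrom == control_bins$chrom) ||
      !all(mutant_bins$bin_start == control_bins$bin_start))
    stop("mutant and control bin tracks differ in structure")
  out <- list()
  for (ch in unique(mutant_bins$chrom)) {
    m <- mutant_bins[mutant_bins$chrom == ch, ]
    c_ <- control_bins[control_bins$chrom == ch, ]
    ord <- order(m$bin_start)
    m <- m[ord, ]; c_ <- c_[ord, ]
    ratio <- (m$depth + cfg$depth_epsilon) / (c_$depth + cfg$depth_epsilon)
    state <- ifelse(ratio <= cfg$del_depth_ratio_max, "DEL",
                    ifelse(ratio >= cfg$dup_depth_ratio_min, "DUP", "none"))
    r <- rle(state)
    ends_i <- cumsum(r$lengths); starts_i <- ends_i - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] == "none") next
      i0 <- starts_i[k]; i1 <- ends_i[k]
      out[[length(out) + 1L]] <- data.frame(
        sv_type = r$values[k], chrom = ch,
        start = m$bin_start[i0], end = m$bin_start[i1] + bin_size - 1L,
        size = m$bin_start[i1] + bin_size - m$bin_start[i0],
        n_bins = i1 - i0 + 1L,
        mean_ratio = mean(ratio[i0:i1]), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sv_type = character(), chrom = character(),
                      start = integer(), end = integer(), size = integer(),
                      n_bins = integer(), mean_ratio = numeric()))
  do.call(rbind, out)
}

#' Classify SVs as genic or intergenic
#'
#' Labels each SV record `genic` when its span overlaps at least one gene
#' interval and `intergenic` otherwise, and flags overlap with genes
#' annotated as transposon/retrotransposon. Translocations are evaluated
#' at their breakpoints (a 1 bp interval at each end).
#'
#' @param svs SV records with `chrom`, `start`, `end` (and `chrom2`,
#'   `pos2` for CTX)
#' @param genes gene-model data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `annotation`), e.g. `reference$genes`
#' @return `svs` with `overlap_class` (`genic`/`intergenic`),
#'   `transposon_overlap` (logical) and `genes_hit` columns
#' @export
sv_gene_overlap <- function(svs, genes) {
  if (!nrow(svs)) {
    svs$overlap_class <- character(0)
    svs$transposon_overlap <- logical(0)
    svs$genes_hit <- character(0)
    return(svs)
  }
  gr_sv <- GenomicRanges::GRanges(svs$chrom,
                                  IRanges::IRanges(svs$start, pmax(svs$start, svs$end)))
  if (nrow(genes)) {
    gr_gene <- GenomicRanges::GRanges(genes$chrom,
                                      IRanges::IRanges(genes$start, genes$end))
    hits <- GenomicRanges::findOverlaps(gr_sv, gr_gene)
    hit_genes <- tapply(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits),
                        function(j) genes$gene_id[j])
    hit_tx <- tapply(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits),
                     function(j) any(genes$annotation[j] == "transposon"))
  } else hit_genes <- hit_tx <- list()
  idx <- as.character(seq_len(nrow(svs)))
  svs$overlap_class <- ifelse(idx %in% names(hit_genes), "genic", "intergenic")
  svs$transposon_overlap <- vapply(idx, function(i)
    i %in% names(hit_tx) && isTRUE(hit_tx[[i]]), logical(1))
  svs$genes_hit <- vapply(idx, function(i)
    if (i %in% names(hit_genes)) paste(hit_genes[[i]], collapse = ",") else "",
    character(1))
  # second breakpoint of inter-chromosomal translocations
  ctx <- which(svs$sv_type == "CTX" & !is.na(svs$chrom2))
  if (length(ctx) && nrow(genes)) {
    gr2 <- GenomicRanges::GRanges(svs$chrom2[ctx],
                                  IRanges::IRanges(svs$pos2[ctx], svs$pos2[ctx]))
    h2 <- GenomicRanges::findOverlaps(gr2, gr_gene)
    if (length(h2)) {
      qi <- unique(S4Vectors::queryHits(h2))
      svs$overlap_class[ctx[qi]] <- "genic"
    }
  }
  rownames(svs) <- NULL
  svs
}

#' Export SV records as BED
#'
#' Converts the internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention.
#'
#' @param svs SV records (`chrom`, `start`, `end`, `sv_type`)
#' @param path output path
#' @return invisibly, `path`
#' @export
write_sv_bed <- function(svs, path) {
  bed <- data.frame(chrom = svs$chrom, start = svs$start - 1L, end = svs$end,
                    name = paste0(svs$sv_type, "_", seq_len(max(1, nrow(svs)))[seq_len(nrow(svs))]))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
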