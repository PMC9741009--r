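#' Annotation configuration
#'
#' @param upstream,downstream window, bp, around a gene within which a
#'   non-genic variant is labeled upstream/downstream (default 5 kb each,
#'   the usual annotation convention); both map to impact MODIFIER
#' @param splice_warn_bp variants within this many bp of an intron/exon
#'   boundary (on the intron side) are labeled intronic with
#'   `splice_proximal = TRUE` (default 2)
#' @return a `radmut_annot_config` list
#' @export
annot_config <- function(upstream = 5000L, downstream = 5000L,
                         splice_warn_bp = 2L) {
  structure(list(upstream = as.integer(upstream),
                 downstream = as.integer(downstream),
                 splice_warn_bp = as.integer(splice_warn_bp)),
            class = "radmut_annot_config")
}

# effect -> impact tier
effect_impact <- c(missense = "MODERATE", nonsense = "HIGH", silent = "LOW",
                   frameshift = "HIGH", inframe_indel = "MODERATE",
                   stop_lost = "HIGH", start_lost = "HIGH",
                   intronic = "MODIFIER", intergenic = "MODIFIER",
                   upstream = "MODIFIER", downstream = "MODIFIER")

# transcription-order exon table and cumulative CDS offsets for one gene
gene_model <- function(reference, gene_id) {
  gene <- reference$genes[reference$genes$gene_id == gene_id, ]
  ex <- reference$cds[reference$cds$gene_id == gene_id, ]
  ex <- ex[order(ex$exon_rank), ]
  len <- ex$end - ex$start + 1L
  list(gene_id = gene_id, chrom = gene$chrom, strand = gene$strand,
       start = gene$start, end = gene$end, exons = ex,
       cum_before = cumsum(c(0L, len))[seq_len(nrow(ex))],
       cds_len = sum(len))
}

# genomic position -> 1-based coordinate in the spliced CDS, NA if not in CDS
cds_coord <- function(model, pos) {
  ex <- model$exons
  for (i in seq_len(nrow(ex))) {
    if (pos >= ex$start[i] && pos <= ex$end[i]) {
      off <- if (model$strand == "+") pos - ex$start[i] else ex$end[i] - pos
      return(model$cum_before[i] + off + 1L)
    }
  }
  NA_integer_
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A")

translate_codon <- function(codon) {
  as.character(Biostrings::GENETIC_CODE[[codon]])
}

classify_coding_snv <- function(model, spliced, pos, ref, alt) {
  cpos <- cds_coord(model, pos)
  ref_c <- if (model$strand == "+") ref else comp_base[[ref]]
  alt_c <- if (model$strand == "+") alt else comp_base[[alt]]
  if (substr(spliced, cpos, cpos) != ref_c)
    stop("reference allele mismatch at ", model$chrom, ":", pos,
         " in gene ", model$gene_id)
  codon_i <- (cpos - 1L) %/% 3L + 1L
  cstart <- 3L * (codon_i - 1L) + 1L
  ref_codon <- substr(spliced, cstart, cstart + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, cpos - cstart + 1L, cpos - cstart + 1L) <- alt_c
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  if (ref_aa == alt_aa) "silent"
  else if (alt_aa == "*") "nonsense"
  else if (ref_aa == "*") "stop_lost"
  else if (codon_i == 1L) "start_lost"
  else "missense"
}

classify_coding_indel <- function(model, spliced, pos, ref, alt) {
  net <- nchar(alt) - nchar(ref)
  if (net %% 3L != 0L) return(list(effect = "frameshift", impact = "HIGH"))
  # in-frame: check for an introduced stop when the edit sits in one exon
  impact <- "MODERATE"
  ex <- model$exons
  span <- c(pos, pos + max(0L, nchar(ref) - 1L))
  one_exon <- any(span[1] >= ex$start & span[2] <= ex$end)
  if (one_exon) {
    # apply the edit on the spliced CDS and look for a premature stop
    if (nchar(ref) > nchar(alt)) {  # deletion: ref = anchor + deleted
      c0 <- cds_coord(model, if (model$strand == "+") pos + 1L else pos + nchar(ref) - 1L)
      c1 <- cds_coord(model, if (model$strand == "+") pos + nchar(ref) - 1L else pos + 1L)
      if (!is.na(c0) && !is.na(c1)) {
        mut <- paste0(substr(spliced, 1L, min(c0, c1) - 1L),
                      substr(spliced, max(c0, c1) + 1L, nchar(spliced)))
        if (has_premature_stop(mut)) impact <- "HIGH"
      }
    } else {                        # insertion after the anchor base
      ins <- substr(alt, 2L, nchar(alt))
      if (model$strand == "-")
        ins <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ins)))
      ca <- cds_coord(model, pos)
      if (!is.na(ca)) {
        at <- if (model$strand == "+") ca else ca - 1L
        mut <- paste0(substr(spliced, 1L, at), ins,
                      substr(spliced, at + 1L, nchar(spliced)))
        if (has_premature_stop(mut)) impact <- "HIGH"
      }
    }
  }
  list(effect = "inframe_indel", impact = impact)
}

has_premature_stop <- function(cds) {
  n <- (nchar(cds) %/% 3L) - 1L  # exclude the terminal codon
  if (n < 1) return(FALSE)
  aa <- vapply(seq_len(n), function(i)
    translate_codon(substr(cds, 3L * i - 2L, 3L * i)), character(1))
  any(aa == "*")
}

#' Classify small variants by predicted functional effect
#'
#' A self-contained codon-level classifier of accepted small variants
#' against the reference genome and its gene models. Effects follow the
#' usual annotation vocabulary: coding SNVs are silent (LOW), missense
#' (MODERATE), nonsense, stop-lost or start-lost (HIGH); coding indels are
#' frameshift (HIGH) when the net length change is not a multiple of 3,
#' otherwise in-frame (MODERATE, upgraded to HIGH if the in-frame edit
#' introduces a premature stop). Variants inside a gene but outside its
#' CDS are intronic; within 5 kb of a gene, upstream/downstream; otherwise
#' intergenic — all MODIFIER. A variant is counted once per gene it hits
#' (per variant-annotation pair), so impact totals can exceed variant
#' totals when annotation windows overlap.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` (normalized
#'   representation) and optionally `line_id`
#' @param reference a `radmut_reference`
#' @param cfg an [annot_config()]
#' @return data.frame: input columns plus `gene_id` (NA for intergenic),
#'   `effect`, `impact`, `splice_proximal`
#' @export
annotate_variants <- function(variants, reference, cfg = annot_config()) {
  stopifnot(inherits(reference, "radmut_reference"))
  genes <- reference$genes
  out <- list()
  models <- list()
  spliced_cache <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    ref_base <- as.character(Biostrings::subseq(reference$genome[[v$chrom]],
                                                v$pos, v$pos + nchar(v$ref) - 1L))
    if (ref_base != v$ref)
      stop("reference allele mismatch at ", v$chrom, ":", v$pos,
           " (expected ", ref_base, ", got ", v$ref, ")")
    span_end <- v$pos + max(0L, nchar(v$ref) - 1L)
    g <- genes[genes$chrom == v$chrom &
               genes$start - cfg$upstream <= span_end &
               genes$end + cfg$downstream >= v$pos, , drop = FALSE]
    if (!nrow(g)) {
      out[[length(out) + 1L]] <- cbind(v, data.frame(
        gene_id = NA_character_, effect = "intergenic",
        impact = "MODIFIER", splice_proximal = FALSE))
      next
    }
    for (j in seq_len(nrow(g))) {
      gid <- g$gene_id[j]
      if (is.null(models[[gid]])) {
        models[[gid]] <- gene_model(reference, gid)
        spliced_cache[[gid]] <- spliced_cds(reference, gid)
      }
      model <- models[[gid]]
      spliced <- spliced_cache[[gid]]
      inside <- span_end >= model$start && v$pos <= model$end
      splice_prox <- FALSE
      if (!inside) {
        before <- span_end < model$start
        effect <- if ((model$strand == "+") == before) "upstream" else "downstream"
      } else {
        is_snv <- nchar(v$ref) == 1L && nchar(v$alt) == 1L
        in_cds <- if (is_snv) !is.na(cds_coord(model, v$pos)) else
          any(vapply(seq_len(nrow(model$exons)), function(e)
            span_end >= model$exons$start[e] && v$pos <= model$exons$end[e],
            logical(1)))
        if (!in_cds) {
          effect <- "intronic"
          d <- min(abs(c(outer(c(v$pos, span_end),
                               c(model$exons$start - 1L, model$exons$end + 1L), "-"))))
          splice_prox <- d < cfg$splice_warn_bp
        } else if (is_snv) {
          effect <- classify_coding_snv(model, spliced, v$pos, v$ref, v$alt)
        } else {
          cls <- classify_coding_indel(model, spliced, v$pos, v$ref, v$alt)
          out[[length(out) + 1L]] <- cbind(v, data.frame(
            gene_id = gid, effect = cls$effect, impact = cls$impact,
            splice_proximal = FALSE))
          next
        }
      }
      out[[length(out) + 1L]] <- cbind(v, data.frame(
        gene_id = gid, effect = effect,
        impact = unname(effect_impact[[effect]]),
        splice_proximal = splice_prox))
    }
  }
  res <- do.call(rbind, c(out, list(NULL)))
  if (is.null(res))
    res <- cbind(variants[0, ], data.frame(gene_id = character(),
                                           effect = character(),
                                           impact = character(),
                                           splice_proximal = logical()))
  rownames(res) <- NULL
  res
}

#' Classify a single SNV against one gene model
#'
#' Convenience wrapper over [annotate_variants()] for one substitution.
#'
#' @param chrom,pos,ref,alt the variant
#' @param reference a `radmut_reference`
#' @param cfg an [annot_config()]
#' @return one-row data.frame with `effect` and `impact`
#' @export
classify_snv <- function(chrom, pos, ref, alt, reference, cfg = annot_config()) {
  annotate_variants(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                               stringsAsFactors = FALSE), reference, cfg)
}

#' @rdname classify_snv
#' @export
classify_indel <- classify_snv

#' Percentage table of effect and impact classes
#'
#' Functional-class percentages are computed over missense + nonsense +
#' silent; impact-tier percentages over HIGH + LOW + MODERATE + MODIFIER.
#' All-zero denominators yield NA percentages rather than an error.
#'
#' @param counts data.frame (or coercible) with columns among `missense`,
#'   `nonsense`, `silent`, `high`, `low`, `moderate`, `modifier`;
#'   additional columns (e.g. `line_id`) are carried through
#' @param digits decimal places for the percentages (default 3)
#' @return `counts` with `pct_<class>` columns appended
#' @export
effect_percentages <- function(counts, digits = 3) {
  counts <- as.data.frame(counts)
  fun <- intersect(c("missense", "nonsense", "silent"), names(counts))
  imp <- intersect(c("high", "low", "moderate", "modifier"), names(counts))
  pct <- function(x, denom) ifelse(denom > 0, round(100 * x / denom, digits), NA_real_)
  if (length(fun)) {
    denom <- rowSums(counts[, fun, drop = FALSE])
    for (f in fun) counts[[paste0("pct_", f)]] <- pct(counts[[f]], denom)
  }
  if (length(imp)) {
    denom <- rowSums(counts[, imp, drop = FALSE])
    for (f in imp) counts[[paste0("pct_", f)]] <- pct(counts[[f]], denom)
  }
  counts
}

#' Tabulate effect and impact counts per line
#'
#' @param annotations output of [annotate_variants()] including `line_id`
#' @return data.frame, one row per line, with per-effect and per-impact
#'   counts and percentages (via [effect_percentages()])
#' @export
effect_count_table <- function(annotations) {
  lines <- sort(unique(annotations$line_id))
  rows <- lapply(lines, function(l) {
    a <- annotations[annotations$line_id == l, ]
    data.frame(line_id = l,
               missense = sum(a$effect == "missense"),
               nonsense = sum(a$effect == "nonsense"),
               silent = sum(a$effect == "silent"),
               high = sum(a$impact == "HIGH"),
               low = sum(a$impact == "LOW"),
               moderate = sum(a$impact == "MODERATE"),
               modifier = sum(a$impact == "MODIFIER"),
               stringsAsFactors = FALSE)
  })
  effect_percentages(do.call(rbind, rows))
}
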