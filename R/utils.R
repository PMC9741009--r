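#' Canonical key for a small variant
#'
#' A small variant's identity is the tuple (chrom, 1-based pos, ref, alt),
#' rendered as `"chrom:pos:ref:alt"`. Records must be normalized (multi-
#' allelics split, indels left-aligned) before keys are compared; see
#' [normalize_variants()].
#'
#' @param chrom chromosome label
#' @param pos 1-based position
#' @param ref,alt allele strings
#' @return character vector of keys
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Classify a small variant as SNV or indel
#'
#' Both alleles of length 1 make an SNV; anything else (including MNVs) is
#' counted with the indels, matching how small-variant spectra are reported
#' for mutagenized populations.
#'
#' @param ref,alt allele strings
#' @return character vector, `"snv"` or `"indel"`
#' @export
small_variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snv", "indel")
}

#' Split multi-allelic records and normalize small-variant representation
#'
#' Multi-allelic rows (comma-separated `alt`) are split into one row per
#' alternate allele. Each ref/alt pair is then reduced to a minimal
#' representation: shared trailing bases are trimmed, then shared leading
#' bases are trimmed while keeping at least one base in each allele and
#' adjusting `pos`. When `reference` (a [Biostrings::DNAStringSet]) is
#' supplied, indels are additionally left-shifted while the flanking
#' reference base allows it, giving `bcftools norm`-style left alignment so
#' that set operations on keys behave like `bcftools isec`.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#' @param reference optional [Biostrings::DNAStringSet] for left alignment
#' @return data.frame with the same columns, one row per normalized allele
#' @export
normalize_variants <- function(variants, reference = NULL) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  multi <- grepl(",", variants$alt, fixed = TRUE)
  if (any(multi)) {
    alts <- strsplit(variants$alt, ",", fixed = TRUE)
    idx <- rep(seq_len(nrow(variants)), lengths(alts))
    variants <- variants[idx, , drop = FALSE]
    variants$alt <- unlist(alts)
    rownames(variants) <- NULL
  }
  out <- variants
  for (i in seq_len(nrow(out))) {
    ref <- out$ref[i]; alt <- out$alt[i]; pos <- out$pos[i]
    # trim shared suffix
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
    }
    # trim shared prefix
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
      pos <- pos + 1L
    }
    # left-align pure indels against the reference (bcftools norm style):
    # truncate equal trailing bases, extending left with the preceding
    # reference base whenever an allele empties
    if (!is.null(reference) && xor(nchar(ref) == 1L, nchar(alt) == 1L) &&
        substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      chromseq <- reference[[out$chrom[i]]]
      repeat {
        nr <- nchar(ref); na <- nchar(alt)
        if (nr > 0L && na > 0L &&
            substr(ref, nr, nr) == substr(alt, na, na)) {
          ref <- substr(ref, 1L, nr - 1L)
          alt <- substr(alt, 1L, na - 1L)
        } else if (nr == 0L || na == 0L) {
          if (pos <= 1L) break
          prev <- as.character(Biostrings::subseq(chromseq, pos - 1L, pos - 1L))
          ref <- paste0(prev, ref); alt <- paste0(prev, alt)
          pos <- pos - 1L
        } else break
      }
      if (nchar(ref) == 0L || nchar(alt) == 0L) {  # hit the chromosome start
        nxt <- as.character(Biostrings::subseq(chromseq, pos + nchar(ref),
                                               pos + nchar(ref)))
        ref <- paste0(ref, nxt); alt <- paste0(alt, nxt)
      }
    }
    out$pos[i] <- pos; out$ref[i] <- ref; out$alt[i] <- alt
  }
  out
}

# deterministic child seeds below 2^31, derived from one master seed
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
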