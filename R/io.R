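#' Write a multi-sample call set as VCF 4.2
#'
#' Serializes a `radmut_callset` (or any long calls data.frame plus sample
#' order) as a minimal multi-sample VCF 4.2 with FORMAT `GT:AD:DP`, the
#' representation consumed by the filtering cascade. AD is written as
#' `ref,alt` with ref depth = DP - alt depth. Output is deterministic:
#' sites sorted by chromosome, position and alt allele, samples in manifest
#' order, no timestamp header.
#'
#' @param callset a `radmut_callset` from [sample_population_calls()]
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_calls_vcf <- function(callset, path) {
  calls <- callset$calls
  samples <- unique(callset$manifest$sample_id)
  sites <- calls[!duplicated(calls$key), c("chrom", "pos", "ref", "alt", "key")]
  sites <- sites[order(sites$chrom, sites$pos, sites$alt), ]
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  # sample-major lookup
  field <- matrix("./.:0,0:0", nrow(sites), length(samples),
                  dimnames = list(sites$key, samples))
  fmt <- sprintf("%s:%d,%d:%d", gt_code[calls$gt],
                 pmax(0L, calls$dp - calls$ad), calls$ad, calls$dp)
  field[cbind(match(calls$key, sites$key), match(calls$sample_id, samples))] <- fmt
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=radmut",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  if (nrow(sites)) {
    body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                  "PASS", ".", "GT:AD:DP",
                  apply(field, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a multi-sample VCF into the long call format
#'
#' Parses a VCF 4.2 file with per-sample `GT`, `AD` and `DP` (e.g. a joint-
#' genotyped population call set) into the long data.frame the filtering
#' cascade operates on. Multi-allelic records are split into one row per
#' alternate allele (the AD entry of that allele is used); records are then
#' normalized with [normalize_variants()] when a reference is given.
#'
#' @param path VCF file path (plain or bgzipped; anything [vcfR::read.vcfR]
#'   accepts)
#' @param reference optional [Biostrings::DNAStringSet] for indel
#'   left-alignment
#' @return long calls data.frame (`chrom`, `pos`, `ref`, `alt`, `key`,
#'   `sample_id`, `gt`, `dp`, `ad`)
#' @export
read_calls_vcf <- function(path, reference = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt_m <- vcfR::extract.gt(v, element = "GT")
  ad_m <- vcfR::extract.gt(v, element = "AD")
  dp_m <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  if (is.null(dp_m)) stop("VCF lacks per-sample DP: ", path)
  samples <- colnames(gt_m)
  rows <- list()
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
    for (a_idx in seq_along(alts)) {
      gt_raw <- gsub("|", "/", gt_m[r, ], fixed = TRUE)
      code <- as.character(a_idx)
      gt <- ifelse(is.na(gt_raw) | gt_raw %in% c("./.", "."), "missing",
            ifelse(gt_raw == paste0(code, "/", code), "hom_alt",
            ifelse(grepl(paste0("(^|/)", code, "(/|$)"), gt_raw), "het",
                   "hom_ref")))
      ad_all <- strsplit(ifelse(is.na(ad_m[r, ]), "", ad_m[r, ]), ",", fixed = TRUE)
      ad <- vapply(ad_all, function(x)
        if (length(x) > a_idx) suppressWarnings(as.integer(x[a_idx + 1L])) else NA_integer_,
        integer(1))
      dp <- as.integer(dp_m[r, ])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[r], pos = as.integer(fix$POS[r]),
        ref = fix$REF[r], alt = alts[a_idx], sample_id = samples,
        gt = unname(gt), dp = ifelse(is.na(dp), 0L, dp),
        ad = ifelse(is.na(ad), 0L, ad), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  norm <- normalize_variants(out[, c("chrom", "pos", "ref", "alt")], reference)
  out$pos <- norm$pos; out$ref <- norm$ref; out$alt <- norm$alt
  out$key <- variant_key(out$chrom, out$pos, out$ref, out$alt)
  rownames(out) <- NULL
  out[, c("chrom", "pos", "ref", "alt", "key", "sample_id", "gt", "dp", "ad")]
}

#' Write truth tables as TSV
#'
#' One file per truth component: founder catalog, induced small variants,
#' database catalog, induced SVs, founder SVs.
#'
#' @param truth a [simulate_truth()] result
#' @param dir output directory
#' @return invisibly, named vector of paths
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(founder = file.path(dir, "truth_founder.tsv"),
             induced = file.path(dir, "truth_induced.tsv"),
             database = file.path(dir, "truth_database.tsv"),
             svs = file.path(dir, "truth_svs.tsv"),
             natural_svs = file.path(dir, "truth_natural_svs.tsv"))
  for (nm in names(paths))
    write.table(truth[[nm]], paths[[nm]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(paths)
}

#' Simulate a complete dataset and (optionally) write it to disk
#'
#' Orchestrates [generate_reference()], [simulate_truth()],
#' [sample_population_calls()] and [simulate_sv_callsets()] under one
#' configuration; with `dir` set, writes reference FASTA + GFF3,
#' multi-sample VCF, SV call TSV, manifest TSV and truth tables. Identical
#' configuration (including seed) gives byte-identical files.
#'
#' @param config a [sim_config()]
#' @param dir optional output directory
#' @return a `radmut_dataset` list: `config`, `reference`, `truth`,
#'   `callset`, `sv_calls`, `manifest` (+ `paths` when written)
#' @export
simulate_dataset <- function(config, dir = NULL) {
  reference <- generate_reference(config)
  truth <- simulate_truth(config, reference)
  callset <- sample_population_calls(config, truth)
  sv_calls <- simulate_sv_callsets(truth, config)
  out <- structure(list(config = config, reference = reference,
                        truth = truth, callset = callset,
                        sv_calls = sv_calls, manifest = callset$manifest),
                   class = "radmut_dataset")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    refp <- write_reference(reference, dir)
    vcf <- file.path(dir, "calls.vcf")
    write_calls_vcf(callset, vcf)
    svp <- file.path(dir, "sv_calls.tsv")
    write.table(sv_calls, svp, sep = "\t", quote = FALSE, row.names = FALSE)
    manp <- file.path(dir, "manifest.tsv")
    write.table(callset$manifest, manp, sep = "\t", quote = FALSE,
                row.names = FALSE)
    tp <- write_truth(truth, dir)
    out$paths <- c(refp, vcf = vcf, sv_calls = svp, manifest = manp, tp)
  }
  out
}
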