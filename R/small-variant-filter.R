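#' Configuration of the small-variant filter
#'
#' Thresholds for depth filtering and allele-ratio zygosity recalibration.
#' Defaults follow the analysis applied to 30x WGS of a replicated
#' mutagenized rice population: minimum per-sample depth 20x; heterozygous
#' calls with *less than* 20% or *more than* 80% of reads supporting the
#' alternate allele re-scored as homozygous reference / homozygous
#' alternate (strict inequalities: fractions exactly at a bound stay
#' heterozygous).
#'
#' @param min_depth minimum per-sample read depth, inclusive (default 20)
#' @param het_low,het_high allele-ratio bounds for keeping a heterozygous
#'   call (defaults 0.20 / 0.80)
#' @param require_both_replicates require an induced mutation to be
#'   observed in both biological replicates of its line (default TRUE)
#' @return a `radmut_filter_config` list
#' @export
filter_config <- function(min_depth = 20L, het_low = 0.20, het_high = 0.80,
                          require_both_replicates = TRUE) {
  stopifnot(min_depth >= 1, het_low > 0, het_high < 1, het_low < het_high)
  structure(list(min_depth = as.integer(min_depth), het_low = het_low,
                 het_high = het_high,
                 require_both_replicates = isTRUE(require_both_replicates)),
            class = "radmut_filter_config")
}

#' Recalibrate zygosity of heterozygous calls by allele ratio
#'
#' Heterozygous calls whose alternate-allele read fraction is below
#' `het_low` are re-scored homozygous reference; above `het_high`,
#' homozygous alternate. The inequalities are strict, so a call at exactly
#' 20% or 80% remains heterozygous. Homozygous calls pass through
#' unchanged; a heterozygous call with zero depth is marked missing. The
#' operation is idempotent.
#'
#' @param calls data.frame with columns `gt` (`hom_ref`/`het`/`hom_alt`/
#'   `missing`), `dp`, `ad`
#' @param cfg a [filter_config()]
#' @return `calls` with recalibrated `gt` and a logical `recalibrated`
#'   column
#' @export
recalibrate_zygosity <- function(calls, cfg = filter_config()) {
  stopifnot(all(c("gt", "dp", "ad") %in% names(calls)))
  if (any(calls$ad > calls$dp, na.rm = TRUE))
    stop("alt depth exceeds total depth in input calls")
  gt <- calls$gt
  het <- gt == "het"
  zero <- het & calls$dp == 0L
  gt[zero] <- "missing"
  frac <- ifelse(calls$dp > 0L, calls$ad / calls$dp, NA_real_)
  to_ref <- het & !zero & frac < cfg$het_low
  to_alt <- het & !zero & frac > cfg$het_high
  gt[to_ref] <- "hom_ref"
  gt[to_alt] <- "hom_alt"
  calls$recalibrated <- (calls$gt != gt)
  calls$gt <- gt
  calls
}

#' Apply the minimum-depth filter
#'
#' A sample's call at a site is usable only if its total depth DP is at
#' least `min_depth` (inclusive: DP = 20 passes the default 20x
#' threshold). Missing genotypes never pass.
#'
#' @param calls data.frame with a `dp` column
#' @param cfg a [filter_config()]
#' @return `calls` with a logical `pass_depth` column
#' @export
depth_filter <- function(calls, cfg = filter_config()) {
  if (!"dp" %in% names(calls))
    stop("calls lack a DP column; depth filtering undefined")
  if (anyNA(calls$dp))
    stop("missing DP for record(s): ",
         paste(utils::head(calls$key[is.na(calls$dp)], 3), collapse = ", "))
  calls$pass_depth <- calls$dp >= cfg$min_depth & calls$gt != "missing"
  calls
}

#' Catalog natural variation from controls and a database VCF
#'
#' The control catalog is the union of non-reference variant keys over all
#' non-irradiated control samples (after depth filtering and zygosity
#' recalibration, applied here); the database catalog is every key in the
#' supplied natural-variation VCF (standing in for a species-wide
#' resequencing database). Both are deduplicated.
#'
#' @param calls long calls data.frame covering the control samples
#' @param control_samples character vector of control sample ids (>= 1)
#' @param database_vcf path to the catalog VCF, or a data.frame with
#'   `chrom`, `pos`, `ref`, `alt` columns, or NULL for an empty catalog
#' @param cfg a [filter_config()]
#' @param reference optional [Biostrings::DNAStringSet] for normalizing
#'   the database records
#' @return list with character vectors `control_catalog` and
#'   `database_catalog`
#' @export
build_natural_catalog <- function(calls, control_samples, database_vcf = NULL,
                                  cfg = filter_config(), reference = NULL) {
  if (length(control_samples) < 1L)
    stop("at least one non-irradiated control sample is required")
  ctl <- calls[calls$sample_id %in% control_samples, ]
  ctl <- depth_filter(recalibrate_zygosity(ctl, cfg), cfg)
  carried <- ctl$pass_depth & ctl$gt %in% c("het", "hom_alt")
  control_catalog <- sort(unique(ctl$key[carried]))
  database_catalog <- character(0)
  if (!is.null(database_vcf)) {
    db <- if (is.data.frame(database_vcf)) database_vcf else {
      v <- vcfR::read.vcfR(database_vcf, verbose = FALSE)
      fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
      data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                 ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
    }
    db <- normalize_variants(db, reference)
    database_catalog <- sort(unique(variant_key(db$chrom, db$pos, db$ref, db$alt)))
  }
  list(control_catalog = control_catalog, database_catalog = database_catalog)
}

#' Run the four-step natural-variation filtering cascade
#'
#' Identifies induced mutations per mutant line from a depth-filtered,
#' zygosity-recalibrated multi-sample call set (both preprocessing steps
#' are applied here). A variant key enters a line's candidate set if any
#' replicate of the line called it non-reference before preprocessing;
#' each candidate is then either accepted or rejected with exactly one
#' reason:
#'
#' 1. `in_control` — key carried by a non-irradiated control;
#' 2. `shared_across_lines` — key carried (non-reference after
#'    recalibration, depth-passing) by samples of more than one mutant
#'    line; sharing is evaluated on each line's carrier set *before*
#'    replicate intersection, so one stray replicate in another line is
#'    enough to disqualify the key everywhere;
#' 3. `replicate_discordant` — key not carried by both replicates of the
#'    line (a missing genotype counts as discordant);
#' 4. `in_database` — key present in the natural-variation database
#'    catalog.
#'
#' Candidates whose carrying calls were all lost upstream are rejected as
#' `allele_ratio_recalibrated_to_ref` (some carrier was recalibrated to
#' reference) or `low_depth` (all carriers failed the depth filter).
#'
#' Accepted keys are split into SNVs (both alleles length 1) and indels.
#' Every candidate appears in exactly one of accepted/rejected per line.
#'
#' @param calls long calls data.frame (`chrom`, `pos`, `ref`, `alt`,
#'   `key`, `sample_id`, `gt`, `dp`, `ad`), already normalized
#' @param manifest data.frame (`sample_id`, `line_id`, `role`) where role
#'   is `mutant_rep` or `control`
#' @param catalogs list from [build_natural_catalog()]
#' @param cfg a [filter_config()]
#' @return a `radmut_catalog` list: `accepted` (data.frame: `line_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `key`, `class`, `zygosity`), `rejected`
#'   (data.frame: `line_id`, `key`, `reason`, `step`), `lines`
#' @export
run_cascade <- function(calls, manifest, catalogs, cfg = filter_config()) {
  stopifnot(all(c("sample_id", "line_id", "role") %in% names(manifest)))
  mut_lines <- unique(manifest$line_id[manifest$role == "mutant_rep"])
  reps_of <- lapply(setNames(mut_lines, mut_lines), function(l)
    manifest$sample_id[manifest$line_id == l & manifest$role == "mutant_rep"])
  if (cfg$require_both_replicates &&
      any(vapply(reps_of, length, integer(1)) != 2L))
    stop("every mutant line must have exactly 2 replicate samples")

  mut_calls <- calls[calls$sample_id %in% unlist(reps_of), ]
  raw_nonref <- mut_calls$gt %in% c("het", "hom_alt")
  proc <- depth_filter(recalibrate_zygosity(mut_calls, cfg), cfg)
  proc$carrier <- proc$pass_depth & proc$gt %in% c("het", "hom_alt")
  proc$line_id <- manifest$line_id[match(proc$sample_id, manifest$sample_id)]

  # carrier keys per line after preprocessing, before replicate intersection
  carrier_keys <- lapply(reps_of, function(smps)
    unique(proc$key[proc$carrier & proc$sample_id %in% smps]))
  carrier_count <- table(unlist(lapply(carrier_keys, unique)))

  site_info <- calls[!duplicated(calls$key),
                     c("chrom", "pos", "ref", "alt", "key")]
  accepted <- list(); rejected <- list()
  for (l in mut_lines) {
    smps <- reps_of[[l]]
    raw_keys <- unique(mut_calls$key[raw_nonref & mut_calls$sample_id %in% smps])
    if (!length(raw_keys)) next
    sub <- proc[proc$sample_id %in% smps & proc$key %in% raw_keys, ]
    post_carriers <- tapply(sub$carrier, sub$key, sum)[raw_keys]
    post_carriers[is.na(post_carriers)] <- 0L
    reason <- rep(NA_character_, length(raw_keys)); names(reason) <- raw_keys
    step <- rep(NA_integer_, length(raw_keys)); names(step) <- raw_keys
    for (k in raw_keys) {
      if (post_carriers[[k]] == 0L) {
        rows <- sub[sub$key == k, ]
        recal_lost <- any(rows$recalibrated & rows$gt == "hom_ref")
        reason[k] <- if (recal_lost) "allele_ratio_recalibrated_to_ref" else "low_depth"
        step[k] <- 0L
      } else if (k %in% catalogs$control_catalog) {
        reason[k] <- "in_control"; step[k] <- 1L
      } else if (carrier_count[[k]] > 1L) {
        reason[k] <- "shared_across_lines"; step[k] <- 2L
      } else if (cfg$require_both_replicates &&
                 post_carriers[[k]] < length(smps)) {
        reason[k] <- "replicate_discordant"; step[k] <- 3L
      } else if (k %in% catalogs$database_catalog) {
        reason[k] <- "in_database"; step[k] <- 4L
      }
    }
    acc_keys <- raw_keys[is.na(reason)]
    rej_keys <- raw_keys[!is.na(reason)]
    if (length(acc_keys)) {
      info <- site_info[match(acc_keys, site_info$key), ]
      zyg <- vapply(acc_keys, function(k) {
        g <- sub$gt[sub$key == k & sub$carrier]
        if (all(g == "hom_alt")) "hom_alt" else "het"
      }, character(1))
      accepted[[l]] <- data.frame(line_id = l, info,
                                  class = small_variant_class(info$ref, info$alt),
                                  zygosity = unname(zyg),
                                  stringsAsFactors = FALSE)
    }
    if (length(rej_keys))
      rejected[[l]] <- data.frame(line_id = l, key = rej_keys,
                                  reason = unname(reason[rej_keys]),
                                  step = unname(step[rej_keys]),
                                  stringsAsFactors = FALSE)
  }
  empty_acc <- data.frame(line_id = character(), chrom = character(),
                          pos = integer(), ref = character(), alt = character(),
                          key = character(), class = character(),
                          zygosity = character())
  empty_rej <- data.frame(line_id = character(), key = character(),
                          reason = character(), step = integer())
  acc <- if (length(accepted)) do.call(rbind, accepted) else empty_acc
  rej <- if (length(rejected)) do.call(rbind, rejected) else empty_rej
  rownames(acc) <- rownames(rej) <- NULL
  structure(list(accepted = acc, rejected = rej, lines = mut_lines),
            class = "radmut_catalog")
}
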