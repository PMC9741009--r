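#' Run the full pipeline on a simulated dataset
#'
#' Simulate -> filter small variants -> consolidate SVs -> annotate
#' effects -> report, under one configuration and one seed. With `out_dir`
#' set, writes all artifacts (reference, call files, truth tables,
#' accepted/rejected variant tables, consensus SVs, annotations, report
#' TSV + JSON summary, and a run manifest with a config hash and per-stage
#' counts). Identical config (including seed) yields identical artifacts.
#'
#' @param config a [sim_config()]
#' @param out_dir optional output directory
#' @param filter_cfg a [filter_config()]
#' @param sv_cfg an [sv_config()]
#' @param annot_cfg an [annot_config()]
#' @return a `radmut_run` list: `dataset`, `catalogs`, `catalog`,
#'   `sv` (consensus), `annotations`, `effects`, `report`, `evaluation`
#' @export
run_all <- function(config, out_dir = NULL, filter_cfg = filter_config(),
                    sv_cfg = sv_config(), annot_cfg = annot_config()) {
  dataset <- simulate_dataset(config, dir = out_dir)
  manifest <- dataset$manifest
  calls <- dataset$callset$calls
  controls <- manifest$sample_id[manifest$role == "control"]
  catalogs <- build_natural_catalog(
    calls, controls,
    database_vcf = dataset$truth$database[, c("chrom", "pos", "ref", "alt")],
    cfg = filter_cfg, reference = dataset$reference$genome)
  catalog <- run_cascade(calls, manifest, catalogs, filter_cfg)
  sv <- sv_consensus(dataset$sv_calls, manifest, sv_cfg)
  sv$records <- if (nrow(sv$records))
    sv_gene_overlap(sv$records, dataset$reference$genes) else sv$records
  annotations <- annotate_variants(catalog$accepted, dataset$reference,
                                   annot_cfg)
  effects <- if (nrow(annotations)) effect_count_table(annotations) else NULL
  genome_size <- config$n_chroms * config$chrom_length
  report <- build_report(catalog, sv$records, manifest,
                         genome_size = genome_size)
  evaluation <- evaluate_against_truth(catalog, sv, dataset$truth, sv_cfg)
  out <- structure(list(dataset = dataset, catalogs = catalogs,
                        catalog = catalog, sv = sv,
                        annotations = annotations, effects = effects,
                        report = report, evaluation = evaluation),
                   class = "radmut_run")
  if (!is.null(out_dir)) {
    write.table(catalog$accepted, file.path(out_dir, "accepted_mutations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(catalog$rejected, file.path(out_dir, "rejected_mutations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sv$records, file.path(out_dir, "consensus_svs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(annotations, file.path(out_dir, "annotations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_report(report, tsv = file.path(out_dir, "spectrum_report.tsv"),
                 json = file.path(out_dir, "spectrum_summary.json"))
    cfg_json <- file.path(out_dir, "run_config.json")
    jsonlite::write_json(config[setdiff(names(config), "lines")], cfg_json,
                         auto_unbox = TRUE, digits = NA)
    manifest_json <- list(
      config_md5 = unname(tools::md5sum(cfg_json)),
      n_samples = nrow(manifest),
      n_sites = length(unique(calls$key)),
      n_accepted = nrow(catalog$accepted),
      n_rejected = nrow(catalog$rejected),
      n_consensus_svs = nrow(sv$records),
      evaluation = evaluation)
    jsonlite::write_json(manifest_json, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Precision and recall of the pipeline against the simulation truth
#'
#' Small variants: the expected accepted set per line is the induced truth
#' minus planted cross-line collisions and database hits (those must be
#' rejected). SVs: a truth SV counts as recovered when a consensus record
#' of the same line and type lies within the merge tolerance at both
#' breakpoints; consensus records not matching any truth SV count against
#' precision. Also reports leakage: collision/database-hit keys that
#' appear in any accepted set (must be 0).
#'
#' @param catalog a `radmut_catalog`
#' @param sv a `radmut_sv_consensus` (or NULL to skip SV metrics)
#' @param truth a `radmut_truth`
#' @param sv_cfg an [sv_config()] (for the matching tolerance)
#' @return list with `small` (precision, recall, n_expected, n_accepted),
#'   `sv` (precision, recall), `leakage`
#' @export
evaluate_against_truth <- function(catalog, sv, truth, sv_cfg = sv_config()) {
  expected <- truth$induced[!truth$induced$collision & !truth$induced$in_database, ]
  exp_pairs <- paste(expected$line_id, expected$key)
  acc_pairs <- paste(catalog$accepted$line_id, catalog$accepted$key)
  tp <- sum(acc_pairs %in% exp_pairs)
  small <- list(precision = if (length(acc_pairs)) tp / length(acc_pairs) else NA,
                recall = if (length(exp_pairs)) tp / length(exp_pairs) else NA,
                n_expected = length(exp_pairs), n_accepted = length(acc_pairs))
  bad_keys <- truth$induced$key[truth$induced$collision | truth$induced$in_database]
  leakage <- sum(catalog$accepted$key %in% bad_keys)
  sv_metrics <- NULL
  if (!is.null(sv)) {
    rec <- sv$records
    tol <- sv_cfg$merge_tolerance
    matched_truth <- logical(nrow(truth$svs))
    matched_rec <- logical(nrow(rec))
    for (i in seq_len(nrow(truth$svs))) {
      t <- truth$svs[i, ]
      b2_t <- if (t$sv_type == "CTX") t$pos2 else t$end
      cand <- which(rec$line_id == t$line_id & rec$sv_type == t$sv_type &
                    rec$chrom == t$chrom)
      for (j in cand) {
        b2_r <- if (rec$sv_type[j] == "CTX") rec$pos2[j] else rec$end[j]
        if (abs(rec$start[j] - t$start) <= tol && abs(b2_r - b2_t) <= tol) {
          matched_truth[i] <- TRUE; matched_rec[j] <- TRUE
        }
      }
    }
    sv_metrics <- list(
      precision = if (nrow(rec)) mean(matched_rec) else NA,
      recall = if (nrow(truth$svs)) mean(matched_truth) else NA,
      n_truth = nrow(truth$svs), n_records = nrow(rec))
  }
  list(small = small, sv = sv_metrics, leakage = leakage)
}

#' Path to a packaged example/benchmark file
#'
#' @param name file name under the package's `extdata`, or empty to list
#' @return path (or vector of available names)
#' @export
radmut_extdata <- function(name = "") {
  if (nzchar(name))
    system.file("extdata", name, package = "radmut", mustWork = TRUE)
  else
    dir(system.file("extdata", package = "radmut"))
}

#' Published per-line mutation spectrum benchmark
#'
#' Counts and printed derived columns for the 11 mutant lines of a
#' replicated gamma/X-ray rice mutagenesis screen (430 Mbp genome): SNV,
#' indel and per-type SV counts together with the printed totals,
#' bp/event frequencies and the footnoted accounting convention
#' (translocations also recorded as origin-locus deletions, already
#' reflected in the printed deletion column). Used as a regression fixture
#' for the report arithmetic.
#'
#' @return data.frame, one row per line
#' @export
load_published_spectrum <- function() {
  read.delim(radmut_extdata("published_spectrum_counts.tsv"),
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Published per-line effect-class benchmark
#'
#' Missense/nonsense/silent and impact-tier counts with their printed
#' percentages for the same 11 mutant lines. Percentages are stored as
#' printed strings so tests can honor the printed precision.
#'
#' @return data.frame, one row per line
#' @export
load_published_effects <- function() {
  read.delim(radmut_extdata("published_effect_counts.tsv"),
             stringsAsFactors = FALSE, check.names = FALSE,
             colClasses = "character")
}

#' Sanger-validation call fixture
#'
#' Encodes a published 34-entry Sanger validation set as sample calls:
#' per entry the genotype call, total depth and alt-supporting depth,
#' plus the published confirmation status. The three allele-ratio
#' negatives carry their footnoted read counts (3/29, 2/21, 2/25) and one
#' negative fails the 20x depth threshold; depths for the 30 confirmed
#' entries are representative synthetic fill-ins (the publication does
#' not print them), chosen once and fixed.
#'
#' @return data.frame, one row per validated call
#' @export
load_validation_calls <- function() {
  read.delim(radmut_extdata("sanger_validation_calls.tsv"),
             stringsAsFactors = FALSE)
}

#' Apply zygosity recalibration and depth filtering to validation calls
#'
#' The preprocessing half of the small-variant filter, as applied to
#' individual validation candidates: recalibrate heterozygous calls by
#' allele ratio, then require the minimum depth. An entry is retained as a
#' candidate mutation when its (possibly recalibrated) genotype is still
#' non-reference and it passes the depth filter.
#'
#' @param calls data.frame with `gt`, `dp`, `ad`
#' @param cfg a [filter_config()]
#' @return `calls` with `retained` (logical) and `drop_reason` columns
#' @export
filter_validation_calls <- function(calls, cfg = filter_config()) {
  proc <- depth_filter(recalibrate_zygosity(calls, cfg), cfg)
  nonref <- proc$gt %in% c("het", "hom_alt")
  proc$retained <- proc$pass_depth & nonref
  proc$drop_reason <- ifelse(proc$retained, "",
    ifelse(!proc$pass_depth, "low_depth", "allele_ratio_recalibrated_to_ref"))
  proc
}
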