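#' Specification of one line in a simulated mutagenized population
#'
#' A line is either a mutant (gamma- or X-ray-treated, exactly two replicate
#' plants sequenced) or a non-irradiated control (zero induced mutations;
#' one or two replicates). Doses follow the treatment series used for
#' seed mutagenesis screens: 0, 75, 150, 300, 450 or 600 Gy.
#'
#' @param line_id line label, e.g. `"M149"`
#' @param treatment `"gamma"`, `"xray"` or `"none"`
#' @param dose_gy absorbed dose in grays; must be 0 when `treatment` is
#'   `"none"`
#' @param n_snv,n_indel,n_sv counts of induced mutations to plant in this
#'   line (0 for controls)
#' @param replicate_ids sample labels; exactly 2 for mutant lines, 1 or 2
#'   for controls
#' @return a `radmut_line_spec` list
#' @export
line_spec <- function(line_id, treatment = c("gamma", "xray", "none"),
                      dose_gy = 0, n_snv = 0, n_indel = 0, n_sv = 0,
                      replicate_ids) {
  treatment <- match.arg(treatment)
  stopifnot(dose_gy %in% c(0, 75, 150, 300, 450, 600))
  if (treatment == "none") {
    if (dose_gy != 0 || n_snv + n_indel + n_sv > 0)
      stop("control lines must have dose 0 and zero induced mutations")
    if (!length(replicate_ids) %in% 1:2)
      stop("control lines take 1 or 2 replicate samples")
  } else {
    if (length(replicate_ids) != 2L)
      stop("mutant line ", line_id, " must have exactly 2 replicate samples")
  }
  structure(list(line_id = line_id, treatment = treatment,
                 dose_gy = dose_gy, n_snv = as.integer(n_snv),
                 n_indel = as.integer(n_indel), n_sv = as.integer(n_sv),
                 replicate_ids = as.character(replicate_ids)),
            class = "radmut_line_spec")
}

#' Default simulated population: 11 mutant lines plus controls
#'
#' Mirrors the design of a replicated gamma/X-ray rice mutagenesis screen:
#' four gamma lines (150-450 Gy), seven X-ray lines (75-150 Gy), two
#' non-irradiated control plants from the same seed bulk. Per-line induced
#' mutation loads are the observed per-line spectra of such a screen scaled
#' by `scale` (default 1/100) so that a desk-scale genome carries a
#' realistic relative spectrum.
#'
#' @param scale multiplier applied to the full-genome per-line loads
#' @return list of [line_spec()] objects
#' @export
default_lines <- function(scale = 0.01) {
  loads <- data.frame(
    line_id = c("M149", "M153", "M166", "M193", "M225", "M232",
                "M238", "M242", "M244", "M314", "M317"),
    treatment = c("gamma", "gamma", "gamma", "gamma", "xray", "xray",
                  "xray", "xray", "xray", "xray", "xray"),
    dose_gy = c(150, 150, 300, 450, 75, 75, 75, 75, 75, 150, 150),
    snv = c(5205, 5054, 3924, 6328, 4389, 6859, 4378, 10619, 7172, 4425, 4216),
    indel = c(1432, 1919, 2884, 1861, 1248, 2188, 3303, 7652, 1984, 1357, 1372),
    sv = c(379, 321, 339, 627, 521, 499, 447, 341, 236, 489, 481)
  )
  mutants <- lapply(seq_len(nrow(loads)), function(i) {
    with(loads[i, ], line_spec(
      line_id, treatment, dose_gy,
      n_snv = max(1L, round(snv * scale)),
      n_indel = max(1L, round(indel * scale)),
      n_sv = max(1L, round(sv * scale)),
      replicate_ids = paste0(line_id, c("_rep1", "_rep2"))
    ))
  })
  c(mutants, list(line_spec("CTRL", "none", 0,
                            replicate_ids = c("ctrl_43801", "ctrl_43802"))))
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. All randomness in
#' the generator flows from `seed`; the same configuration yields
#' byte-identical output files.
#'
#' @param seed master RNG seed (integer)
#' @param n_chroms number of chromosomes
#' @param chrom_length chromosome length in bp (>= 10000)
#' @param n_genes number of protein-coding gene models to place
#' @param natural_variant_density founder natural variants per bp shared by
#'   the whole seed bulk (default 1e-3)
#' @param lines list of [line_spec()]; default [default_lines()]
#' @param depth_mean mean sequencing depth, reads (Poisson; default 30,
#'   matching a 30x whole-genome design)
#' @param het_alt_fraction_mean expected alternate-allele read fraction at a
#'   heterozygous site (default 0.5)
#' @param genotyping_error_rate per-call probability of a miscalled genotype
#'   (default 0)
#' @param induced_het_fraction fraction of induced mutations left
#'   heterozygous after seven selfed generations (default 0.05; selfing
#'   fixes most loci)
#' @param indel_len_range induced indel lengths, bp (default 1-15)
#' @param sv_size_range induced SV sizes, bp (default 179-10000)
#' @param sv_breakpoint_jitter_sd per-caller breakpoint noise SD, bp
#' @param n_sv_callers number of simulated SV callers
#' @param caller_sensitivity probability a given caller reports a true SV in
#'   a given replicate (each true SV is guaranteed by at least one caller)
#' @param sv_fp_rate expected false-positive SV calls per caller per sample
#' @param n_natural_svs founder SVs present in every sample including
#'   controls (exercises the cross-line/control SV filter)
#' @param n_collisions induced small variants copied into a second mutant
#'   line (exercises the cross-line filter; default 0)
#' @param n_database_hits induced small variants also planted in the
#'   natural-variation catalog (exercises database subtraction; default 0)
#' @param n_database_extra catalog-only variants beyond the founder subset
#' @param database_founder_fraction fraction of founder variants present in
#'   the catalog (the catalog stands in for a species-wide database, which
#'   overlaps but does not contain all local founder variation)
#' @param noiseless if TRUE, depths are fixed at `depth_mean` and allele
#'   fractions are honored exactly (no sampling noise) -- the regime in
#'   which the pipeline must achieve precision = recall = 1
#' @return a validated `radmut_sim_config` list
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 500000L,
                       n_genes = 30L, natural_variant_density = 1e-3,
                       lines = default_lines(), depth_mean = 30,
                       het_alt_fraction_mean = 0.5,
                       genotyping_error_rate = 0,
                       induced_het_fraction = 0.05,
                       indel_len_range = c(1L, 15L),
                       sv_size_range = c(179L, 10000L),
                       sv_breakpoint_jitter_sd = 150,
                       n_sv_callers = 3L, caller_sensitivity = 0.9,
                       sv_fp_rate = 1, n_natural_svs = 0L,
                       n_collisions = 0L, n_database_hits = 0L,
                       n_database_extra = 50L,
                       database_founder_fraction = 0.8,
                       noiseless = FALSE) {
  stopifnot(chrom_length >= 10000, n_chroms >= 1,
            natural_variant_density >= 0, depth_mean > 0,
            het_alt_fraction_mean > 0, het_alt_fraction_mean < 1,
            genotyping_error_rate >= 0, genotyping_error_rate < 1,
            induced_het_fraction >= 0, induced_het_fraction <= 1,
            sv_breakpoint_jitter_sd >= 0, n_sv_callers >= 1,
            caller_sensitivity > 0, caller_sensitivity <= 1,
            sv_fp_rate >= 0)
  if (!all(vapply(lines, inherits, logical(1), "radmut_line_spec")))
    stop("`lines` must be a list of line_spec() objects")
  ids <- vapply(lines, `[[`, character(1), "line_id")
  if (anyDuplicated(ids)) stop("duplicated line_id in `lines`")
  samples <- unlist(lapply(lines, `[[`, "replicate_ids"))
  if (anyDuplicated(samples)) stop("duplicated sample id across lines")
  if (!any(vapply(lines, function(l) l$treatment == "none", logical(1))))
    stop("at least one non-irradiated control line is required")
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_genes = as.integer(n_genes),
                 natural_variant_density = natural_variant_density,
                 lines = lines, depth_mean = depth_mean,
                 het_alt_fraction_mean = het_alt_fraction_mean,
                 genotyping_error_rate = genotyping_error_rate,
                 induced_het_fraction = induced_het_fraction,
                 indel_len_range = as.integer(indel_len_range),
                 sv_size_range = as.integer(sv_size_range),
                 sv_breakpoint_jitter_sd = sv_breakpoint_jitter_sd,
                 n_sv_callers = as.integer(n_sv_callers),
                 caller_sensitivity = caller_sensitivity,
                 sv_fp_rate = sv_fp_rate,
                 n_natural_svs = as.integer(n_natural_svs),
                 n_collisions = as.integer(n_collisions),
                 n_database_hits = as.integer(n_database_hits),
                 n_database_extra = as.integer(n_database_extra),
                 database_founder_fraction = database_founder_fraction,
                 noiseless = noiseless),
            class = "radmut_sim_config")
}

#' Sample manifest for a simulated population
#'
#' One row per sequenced sample: which line it belongs to, treatment, dose
#' and role (`mutant_rep` or `control`).
#'
#' @param config a [sim_config()]
#' @return data.frame with columns `sample_id`, `line_id`, `treatment`,
#'   `dose_gy`, `role`
#' @export
sim_manifest <- function(config) {
  rows <- lapply(config$lines, function(l) {
    data.frame(sample_id = l$replicate_ids, line_id = l$line_id,
               treatment = l$treatment, dose_gy = l$dose_gy,
               role = if (l$treatment == "none") "control" else "mutant_rep",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
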