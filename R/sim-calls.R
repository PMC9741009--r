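#' Sample a multi-sample small-variant call set from the truth
#'
#' Emulates the joint-genotyped call matrix of a replicated population
#' sequencing experiment. Every truth site yields one record with per-
#' sample genotype (GT), alt-supporting depth (AD) and total depth (DP).
#' Founder variants are carried by every sample (controls included);
#' induced variants only by the replicates of their line. Total depth is
#' Poisson(`depth_mean`); at a heterozygous site the alt depth is
#' Binomial(DP, `het_alt_fraction_mean`); homozygous sites get small
#' symmetric read noise. With `noiseless = TRUE` depths are fixed and
#' fractions exact, the regime where downstream filtering must recover the
#' truth exactly.
#'
#' @param config a [sim_config()]
#' @param truth a [simulate_truth()] result under the same config
#' @return a `radmut_callset`: list with `calls` (long data.frame: `chrom`,
#'   `pos`, `ref`, `alt`, `key`, `sample_id`, `gt`, `dp`, `ad`) and
#'   `manifest` ([sim_manifest()])
#' @export
sample_population_calls <- function(config, truth) {
  stopifnot(inherits(config, "radmut_sim_config"),
            inherits(truth, "radmut_truth"))
  for (l in config$lines)
    if (l$treatment != "none" && length(l$replicate_ids) != 2L)
      stop("mutant line ", l$line_id, " must have exactly 2 replicates")
  set.seed(derive_seed(config$seed, 3L))
  manifest <- sim_manifest(config)

  sites <- rbind(truth$founder[, c("chrom", "pos", "ref", "alt", "key")],
                 truth$induced[, c("chrom", "pos", "ref", "alt", "key")])
  sites <- sites[!duplicated(sites$key), ]
  sites <- sites[order(sites$chrom, sites$pos, sites$alt), ]
  n_sites <- nrow(sites)
  samples <- manifest$sample_id
  n_samp <- length(samples)

  # genotype matrix: default hom_ref, then founder/induced carriers
  gt <- matrix("hom_ref", n_sites, n_samp,
               dimnames = list(sites$key, samples))
  if (nrow(truth$founder))
    gt[truth$founder$key, ] <- matrix(rep(truth$founder$zygosity, n_samp),
                                      ncol = n_samp)
  if (nrow(truth$induced)) {
    for (i in seq_len(nrow(truth$induced))) {
      reps <- manifest$sample_id[manifest$line_id == truth$induced$line_id[i]]
      gt[truth$induced$key[i], reps] <- truth$induced$zygosity[i]
    }
  }
  if (config$genotyping_error_rate > 0) {
    flip <- which(matrix(runif(n_sites * n_samp) < config$genotyping_error_rate,
                         n_sites, n_samp))
    states <- c("hom_ref", "het", "hom_alt")
    for (ix in flip)
      gt[ix] <- sample(setdiff(states, gt[ix]), 1L)
  }

  gt_vec <- as.vector(gt)
  if (config$noiseless) {
    dp <- rep(as.integer(round(config$depth_mean)), length(gt_vec))
    ad <- integer(length(gt_vec))
    ad[gt_vec == "het"] <- as.integer(round(config$depth_mean *
                                            config$het_alt_fraction_mean))
    ad[gt_vec == "hom_alt"] <- dp[gt_vec == "hom_alt"]
  } else {
    dp <- rpois(length(gt_vec), config$depth_mean)
    ad <- integer(length(gt_vec))
    het <- gt_vec == "het"; homa <- gt_vec == "hom_alt"; homr <- gt_vec == "hom_ref"
    ad[het] <- rbinom(sum(het), dp[het], config$het_alt_fraction_mean)
    ad[homa] <- dp[homa] - rbinom(sum(homa), dp[homa], 0.01)
    ad[homr] <- rbinom(sum(homr), dp[homr], 0.002)
  }
  gt_vec[dp == 0L] <- "missing"

  calls <- data.frame(
    chrom = rep(sites$chrom, n_samp), pos = rep(sites$pos, n_samp),
    ref = rep(sites$ref, n_samp), alt = rep(sites$alt, n_samp),
    key = rep(sites$key, n_samp),
    sample_id = rep(samples, each = n_sites),
    gt = gt_vec, dp = as.integer(dp), ad = as.integer(ad),
    stringsAsFactors = FALSE)
  structure(list(calls = calls, manifest = manifest),
            class = "radmut_callset")
}

#' Simulate per-caller structural-variant call sets
#'
#' Emulates running several SV callers on each replicate of each line.
#' Every truth SV is reported by at least one caller in each replicate;
#' each caller independently reports it with probability
#' `caller_sensitivity`, with breakpoints perturbed by
#' Normal(0, `sv_breakpoint_jitter_sd`) and a supporting-read count drawn
#' high enough for genuine events (Poisson mean 180 for translocations,
#' 90 otherwise). Caller-specific false positives are injected at
#' `sv_fp_rate` expected calls per caller per sample; founder
#' (`natural_svs`) events are emitted for every sample, controls included.
#'
#' @param truth a [simulate_truth()] result
#' @param config the matching [sim_config()]
#' @return data.frame of SV calls: `caller_id`, `line_id`, `sample_id`,
#'   `sv_type`, `chrom`, `start`, `end`, `chrom2`, `pos2`, `size`,
#'   `support`, `origin` (`"truth"`, `"natural"` or `"fp"`), `truth_id`
#' @export
simulate_sv_callsets <- function(truth, config) {
  stopifnot(inherits(truth, "radmut_truth"),
            inherits(config, "radmut_sim_config"))
  if (config$sv_breakpoint_jitter_sd < 0) stop("jitter sd must be >= 0")
  set.seed(derive_seed(config$seed, 4L))
  manifest <- sim_manifest(config)
  callers <- paste0("caller", seq_len(config$n_sv_callers))
  jit <- function(x) {
    if (config$sv_breakpoint_jitter_sd == 0) return(as.integer(x))
    pmax(1L, as.integer(round(x + rnorm(length(x),
                                        sd = config$sv_breakpoint_jitter_sd))))
  }
  rows <- list()
  emit <- function(sv, line_id, sample_id, caller_set, origin) {
    for (cl in caller_set) {
      s <- jit(sv$start); e <- if (sv$sv_type %in% c("INS", "CTX")) s else
        max(s, jit(sv$end))
      p2 <- if (!is.na(sv$pos2)) jit(sv$pos2) else NA_integer_
      supp <- if (sv$sv_type %in% c("ITX", "CTX")) max(1L, rpois(1L, 180))
              else max(1L, rpois(1L, 90))
      rows[[length(rows) + 1L]] <<- data.frame(
        caller_id = cl, line_id = line_id, sample_id = sample_id,
        sv_type = sv$sv_type, chrom = sv$chrom, start = s, end = e,
        chrom2 = sv$chrom2, pos2 = p2,
        size = if (is.na(sv$size)) NA_integer_ else
          if (sv$sv_type == "INS") as.integer(sv$size) else as.integer(e - s + 1L),
        support = supp, origin = origin, truth_id = sv$sv_id,
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(truth$svs))) {
    sv <- truth$svs[i, ]
    reps <- manifest$sample_id[manifest$line_id == sv$line_id]
    for (smp in reps) {
      hit <- callers[runif(length(callers)) < config$caller_sensitivity]
      if (!length(hit)) hit <- sample(callers, 1L)
      emit(sv, sv$line_id, smp, hit, "truth")
    }
  }
  for (i in seq_len(nrow(truth$natural_svs))) {
    sv <- truth$natural_svs[i, ]
    for (j in seq_len(nrow(manifest))) {
      hit <- callers[runif(length(callers)) < config$caller_sensitivity]
      if (!length(hit)) hit <- sample(callers, 1L)
      emit(sv, manifest$line_id[j], manifest$sample_id[j], hit, "natural")
    }
  }
  if (config$sv_fp_rate > 0) {
    chroms <- paste0("chr", seq_len(config$n_chroms))
    for (cl in callers) for (j in seq_len(nrow(manifest))) {
      n_fp <- rpois(1L, config$sv_fp_rate)
      for (k in seq_len(n_fp)) {
        type <- sample(c("DEL", "DUP", "INV", "INS"), 1L)
        size <- as.integer(round(runif(1, config$sv_size_range[1],
                                       config$sv_size_range[2] / 4)))
        ch <- sample(chroms, 1L)
        s <- sample(1000:(config$chrom_length - size - 1000L), 1L)
        fp <- data.frame(sv_type = type, chrom = ch, start = s,
                         end = if (type == "INS") s else s + size - 1L,
                         chrom2 = NA_character_, pos2 = NA_integer_,
                         size = size, sv_id = NA_character_,
                         stringsAsFactors = FALSE)
        # FP support drawn low: most fall below caller thresholds
        emit(fp, manifest$line_id[j], manifest$sample_id[j], cl, "fp")
        rows[[length(rows)]]$support <- max(1L, rpois(1L, 25))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(caller_id = character(), line_id = character(),
               sample_id = character(), sv_type = character(),
               chrom = character(), start = integer(), end = integer(),
               chrom2 = character(), pos2 = integer(), size = integer(),
               support = integer(), origin = character(),
               truth_id = character())
  rownames(out) <- NULL
  out
}

#' Simulate read-depth bins for the depth-scan SV detector
#'
#' Mean depth per genomic bin for one mutant sample and one control.
#' Mutant bins fully inside a homozygous truth DEL drop to near zero;
#' bins inside a DUP double. Gaussian noise emulates mapping/coverage
#' variation.
#'
#' @param truth a [simulate_truth()] result
#' @param config the matching [sim_config()]
#' @param line_id mutant line whose DEL/DUP events shape the mutant track
#' @param bin_size bin width, bp
#' @param noise_sd depth noise SD (reads)
#' @return list of two data.frames (`mutant`, `control`) with columns
#'   `chrom`, `bin_start`, `depth`
#' @export
simulate_depth_bins <- function(truth, config, line_id, bin_size = 1000L,
                                noise_sd = 1.5) {
  set.seed(derive_seed(config$seed, 5L))
  chroms <- paste0("chr", seq_len(config$n_chroms))
  svs <- truth$svs[truth$svs$line_id == line_id &
                   truth$svs$sv_type %in% c("DEL", "DUP"), ]
  out_m <- list(); out_c <- list()
  for (ch in chroms) {
    starts <- seq(1L, config$chrom_length, by = bin_size)
    depth_c <- pmax(0, rnorm(length(starts), config$depth_mean, noise_sd))
    mult <- rep(1, length(starts))
    for (i in seq_len(nrow(svs))) {
      if (svs$chrom[i] != ch) next
      inside <- starts >= svs$start[i] & (starts + bin_size - 1L) <= svs$end[i]
      mult[inside] <- if (svs$sv_type[i] == "DEL") 0.02 else 2
    }
    depth_m <- pmax(0, rnorm(length(starts), config$depth_mean * mult, noise_sd))
    out_c[[ch]] <- data.frame(chrom = ch, bin_start = starts, depth = depth_c)
    out_m[[ch]] <- data.frame(chrom = ch, bin_start = starts, depth = depth_m)
  }
  list(mutant = do.call(rbind, out_m), control = do.call(rbind, out_c))
}
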