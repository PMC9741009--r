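#' Generate the ground truth for a simulated population
#'
#' Plants three classes of variation on the reference: (i) founder natural
#' variants shared by the entire seed bulk (all samples, controls
#' included), (ii) line-specific induced small variants (SNVs and 1-15 bp
#' indels), (iii) line-specific induced structural variants. Also builds
#' the natural-variation catalog standing in for a species-wide database:
#' a subset of the founder variants plus catalog-only variants.
#'
#' Optional adversarial features for validating the filtering cascade:
#' cross-line collisions (`n_collisions` induced variants copied into a
#' second mutant line), catalog hits (`n_database_hits` induced variants
#' also present in the database), and founder SVs shared by every sample
#' (`n_natural_svs`).
#'
#' All small-variant records are normalized ([normalize_variants()]) so
#' truth keys are directly comparable with pipeline keys.
#'
#' @param config a [sim_config()]
#' @param reference a [generate_reference()] result under the same config
#' @return a `radmut_truth` list: `founder`, `induced`, `database`
#'   (data.frames of small variants), `svs` and `natural_svs` (data.frames
#'   of SVRecords)
#' @export
simulate_truth <- function(config, reference) {
  stopifnot(inherits(config, "radmut_sim_config"),
            inherits(reference, "radmut_reference"))
  set.seed(derive_seed(config$seed, 2L))
  genome <- reference$genome
  chroms <- names(genome)
  chrom_len <- setNames(Biostrings::width(genome), chroms)

  # draw candidate positions with >= 20 bp spacing so indels never overlap
  free_positions <- function(ch, n_needed_guess) {
    pos <- sort(sample(30:(chrom_len[[ch]] - 30L), min(n_needed_guess * 3L,
                                                       chrom_len[[ch]] %/% 25L)))
    pos[c(TRUE, diff(pos) >= 20L)]
  }
  pools <- lapply(chroms, function(ch) free_positions(ch, 2000L))
  names(pools) <- chroms
  take_positions <- function(n) {
    # draw n (chrom, pos) pairs from the remaining pools
    avail <- vapply(pools, length, integer(1))
    if (sum(avail) < n) stop("chromosomes too short for requested variant load")
    ch_draw <- sample(rep(chroms, avail), n)
    out <- data.frame(chrom = character(n), pos = integer(n))
    for (ch in chroms) {
      k <- sum(ch_draw == ch)
      if (k == 0) next
      idx <- sample(seq_along(pools[[ch]]), k)
      out$chrom[ch_draw == ch] <- ch
      out$pos[ch_draw == ch] <- pools[[ch]][idx]
      pools[[ch]] <<- pools[[ch]][-idx]
    }
    out
  }

  make_small <- function(loci, frac_indel) {
    n <- nrow(loci)
    is_indel <- runif(n) < frac_indel
    ref <- alt <- character(n)
    for (i in seq_len(n)) {
      base <- as.character(Biostrings::subseq(genome[[loci$chrom[i]]],
                                              loci$pos[i], loci$pos[i]))
      if (!is_indel[i]) {
        ref[i] <- base
        alt[i] <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
      } else {
        len <- sample(config$indel_len_range[1]:config$indel_len_range[2], 1L)
        if (runif(1) < 0.5) {  # deletion, anchored on the base before
          ref[i] <- as.character(Biostrings::subseq(genome[[loci$chrom[i]]],
                                                    loci$pos[i], loci$pos[i] + len))
          alt[i] <- base
        } else {               # insertion
          ref[i] <- base
          alt[i] <- paste0(base, paste(sample(c("A", "C", "G", "T"), len,
                                              replace = TRUE), collapse = ""))
        }
      }
    }
    df <- data.frame(chrom = loci$chrom, pos = loci$pos, ref = ref, alt = alt,
                     stringsAsFactors = FALSE)
    df <- normalize_variants(df, genome)
    df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
    df$class <- small_variant_class(df$ref, df$alt)
    df
  }

  # founder natural variation, shared by the whole bulk
  n_founder <- rpois(1L, config$natural_variant_density * sum(chrom_len))
  founder <- make_small(take_positions(n_founder), frac_indel = 0.15)
  founder$zygosity <- "hom_alt"

  # induced small variants per mutant line
  mutants <- Filter(function(l) l$treatment != "none", config$lines)
  induced <- list()
  for (l in mutants) {
    n <- l$n_snv + l$n_indel
    if (n == 0) next
    loci <- take_positions(n)
    # first n_snv loci as SNVs, rest as indels (exact per-line class counts)
    snv_part <- make_small(loci[seq_len(l$n_snv), , drop = FALSE], frac_indel = 0)
    ind_part <- if (l$n_indel > 0)
      make_small(loci[l$n_snv + seq_len(l$n_indel), , drop = FALSE], frac_indel = 1)
    else NULL
    df <- rbind(snv_part, ind_part)
    df$line_id <- l$line_id
    df$zygosity <- ifelse(runif(nrow(df)) < config$induced_het_fraction,
                          "het", "hom_alt")
    induced[[l$line_id]] <- df
  }
  induced <- if (length(induced)) do.call(rbind, induced) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), key = character(), class = character(),
               line_id = character(), zygosity = character())
  rownames(induced) <- NULL
  induced$collision <- rep(FALSE, nrow(induced))
  induced$in_database <- rep(FALSE, nrow(induced))

  # cross-line collisions: copy an induced variant into another mutant line
  if (config$n_collisions > 0 && nrow(induced) > 0 && length(mutants) > 1) {
    pick <- sample(seq_len(nrow(induced)), config$n_collisions)
    for (i in pick) {
      other <- sample(setdiff(vapply(mutants, `[[`, character(1), "line_id"),
                              induced$line_id[i]), 1L)
      copy <- induced[i, ]
      copy$line_id <- other
      induced$collision[i] <- TRUE
      copy$collision <- TRUE
      induced <- rbind(induced, copy)
    }
    rownames(induced) <- NULL
  }

  # natural-variation catalog: founder subset + catalog-only + planted hits
  db_founder <- founder[runif(nrow(founder)) < config$database_founder_fraction,
                        c("chrom", "pos", "ref", "alt", "key")]
  db_extra <- if (config$n_database_extra > 0) {
    extra <- make_small(take_positions(config$n_database_extra), frac_indel = 0.15)
    extra[, c("chrom", "pos", "ref", "alt", "key")]
  } else NULL
  database <- rbind(db_founder, db_extra)
  if (config$n_database_hits > 0 && nrow(induced) > 0) {
    hit_rows <- sample(which(!induced$collision), config$n_database_hits)
    induced$in_database[hit_rows] <- TRUE
    database <- rbind(database,
                      induced[hit_rows, c("chrom", "pos", "ref", "alt", "key")])
  }
  database <- database[!duplicated(database$key), ]
  rownames(database) <- NULL

  # induced SVs per line; sizes bounded by chromosome length
  sv_types <- c("DEL", "DUP", "INV", "INS", "ITX", "CTX")
  sv_weights <- c(0.72, 0.06, 0.05, 0.06, 0.04, 0.07)
  draw_svs <- function(line_id, n) {
    if (n == 0) return(NULL)
    type <- sample(sv_types, n, replace = TRUE, prob = sv_weights)
    if (config$n_chroms < 2) type[type == "CTX"] <- "ITX"
    size <- as.integer(round(runif(n, config$sv_size_range[1],
                                   min(config$sv_size_range[2],
                                       config$chrom_length %/% 4))))
    chrom <- sample(chroms, n, replace = TRUE)
    start <- end <- integer(n); chrom2 <- NA_character_; pos2 <- NA_integer_
    chrom2 <- rep(NA_character_, n); pos2 <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      L <- chrom_len[[chrom[i]]]
      if (type[i] == "CTX") {
        start[i] <- end[i] <- sample(2000:(L - 2000L), 1L)
        chrom2[i] <- sample(setdiff(chroms, chrom[i]), 1L)
        pos2[i] <- sample(2000:(chrom_len[[chrom2[i]]] - 2000L), 1L)
        size[i] <- NA_integer_
      } else if (type[i] == "INS") {
        start[i] <- end[i] <- sample(2000:(L - 2000L), 1L)
      } else {
        start[i] <- sample(2000:(L - size[i] - 2000L), 1L)
        end[i] <- start[i] + size[i] - 1L
      }
    }
    data.frame(line_id = line_id, sv_type = type, chrom = chrom,
               start = start, end = end, chrom2 = chrom2, pos2 = pos2,
               size = size, stringsAsFactors = FALSE)
  }
  svs <- do.call(rbind, c(lapply(mutants, function(l) draw_svs(l$line_id, l$n_sv)),
                          list(NULL)))
  if (is.null(svs))
    svs <- data.frame(line_id = character(), sv_type = character(),
                      chrom = character(), start = integer(), end = integer(),
                      chrom2 = character(), pos2 = integer(), size = integer())
  svs$sv_id <- if (nrow(svs)) sprintf("tsv%04d", seq_len(nrow(svs))) else character(0)

  natural_svs <- draw_svs("__founder__", config$n_natural_svs)
  if (is.null(natural_svs))
    natural_svs <- svs[0, setdiff(names(svs), "sv_id")]
  if (nrow(natural_svs))
    natural_svs$sv_id <- sprintf("nsv%04d", seq_len(nrow(natural_svs)))
  else natural_svs$sv_id <- character(0)

  structure(list(founder = founder, induced = induced, database = database,
                 svs = svs, natural_svs = natural_svs),
            class = "radmut_truth")
}
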