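# Shared fixtures and independent oracles for the test suite.

# small population: 3 mutant lines x 2 replicates + 1 control line (2 samples)
tiny_config <- function(seed = 11, ...) {
  defaults <- list(
    seed = seed, n_chroms = 2L, chrom_length = 60000L, n_genes = 8L,
    natural_variant_density = 5e-4,
    lines = c(
      lapply(1:3, function(i) line_spec(
        paste0("L", i), treatment = "gamma", dose_gy = 150,
        n_snv = 5, n_indel = 3, n_sv = 2,
        replicate_ids = paste0("L", i, c("a", "b")))),
      list(line_spec("C", "none", replicate_ids = c("c1", "c2")))),
    noiseless = TRUE, sv_breakpoint_jitter_sd = 0, sv_fp_rate = 0,
    n_database_extra = 10L)
  args <- list(...)
  defaults[names(args)] <- args   # replace wholesale (modifyList would
  do.call(sim_config, defaults)   # merge the `lines` lists element-wise)
}

# build a long calls data.frame from a compact spec:
# rows of (key, sample_id, gt, dp, ad); site alleles derived from the key
make_calls <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(key = r[[1]], sample_id = r[[2]], gt = r[[3]],
               dp = as.integer(r[[4]]), ad = as.integer(r[[5]]),
               stringsAsFactors = FALSE)))
  parts <- strsplit(df$key, ":", fixed = TRUE)
  df$chrom <- vapply(parts, `[`, "", 1L)
  df$pos <- as.integer(vapply(parts, `[`, "", 2L))
  df$ref <- vapply(parts, `[`, "", 3L)
  df$alt <- vapply(parts, `[`, "", 4L)
  df[, c("chrom", "pos", "ref", "alt", "key", "sample_id", "gt", "dp", "ad")]
}

two_line_manifest <- function() {
  data.frame(
    sample_id = c("Aa", "Ab", "Ba", "Bb", "c1"),
    line_id = c("A", "A", "B", "B", "C"),
    treatment = c(rep("gamma", 4), "none"),
    dose_gy = c(rep(150, 4), 0),
    role = c(rep("mutant_rep", 4), "control"),
    stringsAsFactors = FALSE)
}

# ---- independent oracle: cascade acceptance as pure set predicates --------
# carriers: named list line -> character matrix-ish list sample -> keys carried
oracle_cascade_accept <- function(carrier_by_sample, reps_of, control_cat, db_cat,
                                  order = 1:4) {
  carrier_by_line <- lapply(reps_of, function(s)
    unique(unlist(carrier_by_sample[s])))
  share_count <- table(unlist(lapply(carrier_by_line, unique)))
  lapply(reps_of, function(smps) {
    keys <- unique(unlist(carrier_by_sample[smps]))
    for (step in order) {
      keys <- switch(step,
        setdiff(keys, control_cat),                                  # 1
        keys[share_count[keys] <= 1L],                               # 2
        intersect(keys, Reduce(intersect, carrier_by_sample[smps])), # 3
        setdiff(keys, db_cat))                                       # 4
    }
    sort(keys)
  })
}

# ---- independent oracle: brute-force single-linkage clustering ------------
# transitive closure over the all-pairs linkage relation
oracle_cluster <- function(svs, tol) {
  n <- nrow(svs)
  b2 <- ifelse(svs$sv_type == "CTX", svs$pos2, svs$end)
  link <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    svs$sv_type[i] == svs$sv_type[j] && svs$chrom[i] == svs$chrom[j] &&
      identical(svs$chrom2[i], svs$chrom2[j]) &&
      abs(svs$start[i] - svs$start[j]) <= tol && abs(b2[i] - b2[j]) <= tol
  }))
  repeat {
    nxt <- (link %*% link) > 0
    if (identical(nxt, link)) break
    link <- nxt
  }
  match(apply(link, 1, function(r) paste(which(r), collapse = ",")),
        unique(apply(link, 1, function(r) paste(which(r), collapse = ","))))
}

# ---- independent oracle: protein-diff effect classification ---------------
# Translates the full mutant vs reference CDS (rebuilt from an edited
# chromosome string) and diffs the proteins. Indels must lie fully inside
# one CDS exon.
oracle_effect <- function(reference, gene_id, chrom, pos, ref, alt) {
  gene <- reference$genes[reference$genes$gene_id == gene_id, ]
  ex <- reference$cds[reference$cds$gene_id == gene_id, ]
  ex <- ex[order(ex$start), ]
  chromseq <- as.character(reference$genome[[chrom]])
  net <- nchar(alt) - nchar(ref)
  mutated <- paste0(substr(chromseq, 1, pos - 1), alt,
                    substr(chromseq, pos + nchar(ref), nchar(chromseq)))
  # shift exon coordinates located after the edit
  ex_mut <- ex
  edit_start <- pos
  for (i in seq_len(nrow(ex_mut))) {
    if (ex_mut$start[i] > edit_start) ex_mut$start[i] <- ex_mut$start[i] + net
    if (ex_mut$end[i] >= edit_start) ex_mut$end[i] <- ex_mut$end[i] + net
  }
  splice <- function(seqchar, exdf) {
    chunks <- vapply(seq_len(nrow(exdf)), function(i)
      substr(seqchar, exdf$start[i], exdf$end[i]), character(1))
    s <- paste(chunks, collapse = "")
    if (gene$strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }
  ref_cds <- splice(chromseq, ex)
  mut_cds <- splice(mutated, ex_mut)
  aa <- function(s) {
    n <- nchar(s) %/% 3
    if (n == 0) return("")
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, 1, 3 * n)), no.init.codon = TRUE))
  }
  ref_aa <- aa(ref_cds); mut_aa <- aa(mut_cds)
  if (nchar(ref) == 1 && nchar(alt) == 1) {
    if (ref_aa == mut_aa) return(list(effect = "silent", impact = "LOW"))
    d <- which(strsplit(ref_aa, "")[[1]] != strsplit(mut_aa, "")[[1]])[1]
    ref_d <- substr(ref_aa, d, d); mut_d <- substr(mut_aa, d, d)
    if (mut_d == "*") return(list(effect = "nonsense", impact = "HIGH"))
    if (ref_d == "*") return(list(effect = "stop_lost", impact = "HIGH"))
    if (d == 1) return(list(effect = "start_lost", impact = "HIGH"))
    return(list(effect = "missense", impact = "MODERATE"))
  }
  if (net %% 3 != 0) return(list(effect = "frameshift", impact = "HIGH"))
  internal <- substr(mut_aa, 1, nchar(mut_aa) - 1)
  impact <- if (grepl("*", internal, fixed = TRUE)) "HIGH" else "MODERATE"
  list(effect = "inframe_indel", impact = impact)
}

# random coding variants inside CDS exons of a reference (interior margin
# keeps indels inside one exon and away from splice boundaries)
random_coding_variants <- function(reference, n, seed, margin = 10L,
                                   indel_frac = 0.4) {
  set.seed(seed)
  ex <- reference$cds
  ex <- ex[ex$end - ex$start + 1L >= 2L * margin + 10L, ]
  out <- list()
  for (i in seq_len(n)) {
    r <- ex[sample(nrow(ex), 1L), ]
    gene <- reference$genes[reference$genes$gene_id == r$gene_id, ]
    pos <- sample((r$start + margin):(r$end - margin), 1L)
    base <- as.character(Biostrings::subseq(reference$genome[[gene$chrom]],
                                            pos, pos))
    if (runif(1) > indel_frac) {
      alt <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
      ref <- base
    } else {
      len <- sample(1:6, 1L)
      if (runif(1) < 0.5) {
        ref <- as.character(Biostrings::subseq(reference$genome[[gene$chrom]],
                                               pos, pos + len))
        alt <- base
      } else {
        ref <- base
        alt <- paste0(base, paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = ""))
      }
    }
    out[[i]] <- data.frame(gene_id = r$gene_id, chrom = gene$chrom, pos = pos,
                           ref = ref, alt = alt, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# printed-precision comparison: TRUE when x matches the printed string at
# the number of decimals it carries
matches_printed <- function(x, printed) {
  dec <- nchar(sub("^[^.]*[.]?", "", printed))
  abs(x - as.numeric(printed)) <= 0.5 * 10^(-dec) + 1e-9
}
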