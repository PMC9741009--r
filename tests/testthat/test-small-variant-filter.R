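test_that("allele-ratio recalibration re-scores extreme heterozygous calls", {
  cfg <- filter_config()
  calls <- data.frame(
    gt = c("het", "het", "het", "het", "het", "hom_alt", "het"),
    dp = c(29L, 21L, 30L, 20L, 30L, 25L, 0L),
    ad = c(3L, 2L, 15L, 4L, 25L, 25L, 0L))
  out <- recalibrate_zygosity(calls, cfg)
  expect_equal(out$gt,
               c("hom_ref",  # 3/29 = 10.3% < 20%
                 "hom_ref",  # 2/21 = 9.5%
                 "het",      # 15/30 = 50%, unchanged
                 "het",      # 4/20 = exactly 20%: strict inequality keeps het
                 "hom_alt",  # 25/30 = 83.3% > 80%
                 "hom_alt",  # homozygous calls untouched
                 "missing")) # zero-depth het is unscorable
  expect_equal(out$recalibrated, c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
  # exactly at the upper bound stays het too
  at80 <- recalibrate_zygosity(data.frame(gt = "het", dp = 30L, ad = 24L), cfg)
  expect_equal(at80$gt, "het")
  # idempotent
  expect_equal(recalibrate_zygosity(out, cfg)$gt, out$gt)
  expect_error(recalibrate_zygosity(data.frame(gt = "het", dp = 10L, ad = 11L)),
               "exceeds")
})

test_that("depth filter is inclusive at the threshold and errors on absent DP", {
  cfg <- filter_config()
  calls <- data.frame(key = c("k1", "k2", "k3"),
                      gt = c("het", "het", "missing"),
                      dp = c(20L, 19L, 25L), ad = c(10L, 9L, 0L))
  out <- depth_filter(calls, cfg)
  expect_equal(out$pass_depth, c(TRUE, FALSE, FALSE))
  expect_error(depth_filter(data.frame(gt = "het", ad = 1L), cfg), "DP")
  expect_error(depth_filter(data.frame(key = "kx", gt = "het",
                                       dp = NA_integer_, ad = 1L), cfg), "kx")
})

test_that("natural catalogs take the union over controls and the database file", {
  calls <- make_calls(
    list("chr1:10:A:G", "c1", "hom_alt", 30, 30),
    list("chr1:10:A:G", "c2", "hom_alt", 28, 28),
    list("chr1:20:C:T", "c1", "het", 30, 15),
    list("chr1:30:G:A", "c2", "hom_alt", 30, 30),
    list("chr1:40:T:C", "c1", "hom_alt", 10, 10),   # fails depth: not cataloged
    list("chr1:50:A:C", "c2", "het", 30, 2))        # recalibrated to ref
  cat <- build_natural_catalog(calls, c("c1", "c2"),
                               database_vcf = data.frame(
                                 chrom = "chr1", pos = c(100L, 110L),
                                 ref = "A", alt = "T"))
  expect_setequal(cat$control_catalog,
                  c("chr1:10:A:G", "chr1:20:C:T", "chr1:30:G:A"))
  expect_setequal(cat$database_catalog, c("chr1:100:A:T", "chr1:110:A:T"))
  # two identical controls: union equals either set
  cat2 <- build_natural_catalog(calls[calls$sample_id == "c1", ],
                                "c1", NULL)
  expect_setequal(cat2$control_catalog, c("chr1:10:A:G", "chr1:20:C:T"))
  expect_error(build_natural_catalog(calls, character(0)), "control")
})

test_that("cascade assigns each candidate exactly one fate with the right reason", {
  man <- two_line_manifest()
  calls <- make_calls(
    # k_ctl: in both replicates of A but carried by control -> in_control
    list("chr1:100:A:G", "Aa", "hom_alt", 30, 30),
    list("chr1:100:A:G", "Ab", "hom_alt", 30, 30),
    list("chr1:100:A:G", "c1", "hom_alt", 30, 30),
    # k_shared: both reps of A, one rep of B -> shared for BOTH lines
    list("chr1:200:C:T", "Aa", "hom_alt", 30, 30),
    list("chr1:200:C:T", "Ab", "hom_alt", 30, 30),
    list("chr1:200:C:T", "Ba", "het", 30, 15),
    # k_disc: only one replicate of A -> replicate_discordant
    list("chr1:300:G:A", "Aa", "hom_alt", 30, 30),
    # k_db: clean in A but in database -> in_database
    list("chr1:400:T:C", "Aa", "hom_alt", 30, 30),
    list("chr1:400:T:C", "Ab", "het", 30, 14),
    # k_ok: accepted for A
    list("chr1:500:A:T", "Aa", "hom_alt", 30, 30),
    list("chr1:500:A:T", "Ab", "hom_alt", 29, 29),
    # k_ratio: het 2/25 in both reps of B -> recalibrated away
    list("chr1:600:G:C", "Ba", "het", 25, 2),
    list("chr1:600:G:C", "Bb", "het", 25, 2),
    # k_lowdp: carried by B but below 20x in both reps -> low_depth
    list("chr1:700:C:G", "Ba", "hom_alt", 12, 12),
    list("chr1:700:C:G", "Bb", "hom_alt", 15, 15),
    # k_okB: accepted indel for B
    list("chr1:800:CTT:C", "Ba", "hom_alt", 30, 30),
    list("chr1:800:CTT:C", "Bb", "het", 30, 16))
  catalogs <- list(control_catalog = "chr1:100:A:G",
                   database_catalog = "chr1:400:T:C")
  res <- run_cascade(calls, man, catalogs, filter_config())
  acc <- res$accepted; rej <- res$rejected
  expect_setequal(acc$key[acc$line_id == "A"], "chr1:500:A:T")
  expect_setequal(acc$key[acc$line_id == "B"], "chr1:800:CTT:C")
  expect_equal(acc$class[acc$key == "chr1:800:CTT:C"], "indel")
  expect_equal(acc$class[acc$key == "chr1:500:A:T"], "snv")
  reason_of <- function(l, k) rej$reason[rej$line_id == l & rej$key == k]
  expect_equal(reason_of("A", "chr1:100:A:G"), "in_control")
  expect_equal(reason_of("A", "chr1:200:C:T"), "shared_across_lines")
  expect_equal(reason_of("B", "chr1:200:C:T"), "shared_across_lines")
  expect_equal(reason_of("A", "chr1:300:G:A"), "replicate_discordant")
  expect_equal(reason_of("A", "chr1:400:T:C"), "in_database")
  expect_equal(reason_of("B", "chr1:600:G:C"), "allele_ratio_recalibrated_to_ref")
  expect_equal(reason_of("B", "chr1:700:C:G"), "low_depth")
  # conservation: every candidate key of a line is accepted or rejected once
  for (l in c("A", "B")) {
    cand <- unique(calls$key[calls$gt != "hom_ref" &
                             calls$sample_id %in% man$sample_id[man$line_id == l]])
    got <- c(acc$key[acc$line_id == l], rej$key[rej$line_id == l])
    expect_setequal(got, cand)
    expect_equal(anyDuplicated(got), 0L)
  }
})

test_that("cascade equals the set-predicate oracle under every step ordering", {
  set.seed(404)
  for (trial in 1:8) {
    n_keys <- 30L
    keys <- sprintf("chr1:%d:A:G", seq_len(n_keys) * 10L)
    man <- two_line_manifest()
    mut_samples <- man$sample_id[man$role == "mutant_rep"]
    # random carrier structure (hom_alt calls at 30x pass all preprocessing)
    rows <- list()
    for (s in mut_samples) {
      carried <- keys[runif(n_keys) < 0.35]
      for (k in carried)
        rows[[length(rows) + 1L]] <- list(k, s, "hom_alt", 30, 30)
    }
    if (!length(rows)) next
    calls <- do.call(make_calls, rows)
    control_cat <- sample(keys, 5L)
    db_cat <- sample(keys, 5L)
    res <- run_cascade(calls, man,
                       list(control_catalog = control_cat,
                            database_catalog = db_cat), filter_config())
    carrier_by_sample <- lapply(setNames(mut_samples, mut_samples), function(s)
      unique(calls$key[calls$sample_id == s]))
    reps_of <- list(A = c("Aa", "Ab"), B = c("Ba", "Bb"))
    perms <- list(1:4, 4:1, c(2, 1, 4, 3), c(3, 1, 2, 4), c(4, 2, 3, 1))
    for (p in perms) {
      want <- oracle_cascade_accept(carrier_by_sample, reps_of,
                                    control_cat, db_cat, order = p)
      for (l in names(reps_of))
        expect_equal(sort(res$accepted$key[res$accepted$line_id == l]),
                     want[[l]], label = paste("trial", trial, "line", l,
                                              "perm", paste(p, collapse = "")))
    }
  }
})

test_that("multi-allelic records split and indels left-align to isec-style keys", {
  v <- data.frame(chrom = "chr1", pos = 5L, ref = "A", alt = "G,T")
  out <- normalize_variants(v)
  expect_equal(out$alt, c("G", "T"))
  # shared prefix/suffix trimming
  v2 <- normalize_variants(data.frame(chrom = "chr1", pos = 10L,
                                      ref = "CAG", alt = "CTG"))
  expect_equal(v2$pos, 11L); expect_equal(v2$ref, "A"); expect_equal(v2$alt, "T")
  # left alignment in a homopolymer: deleting one A of AAAA shifts left
  genome <- Biostrings::DNAStringSet(c(chr1 = "GGTAAAACGT"))
  v3 <- normalize_variants(data.frame(chrom = "chr1", pos = 6L,
                                      ref = "AA", alt = "A"), genome)
  expect_equal(v3$pos, 3L)
  expect_equal(v3$ref, "TA"); expect_equal(v3$alt, "T")
})

test_that("missing genotype in one replicate counts as discordant", {
  man <- two_line_manifest()
  calls <- make_calls(
    list("chr1:100:A:G", "Aa", "hom_alt", 30, 30),
    list("chr1:100:A:G", "Ab", "missing", 0, 0))
  res <- run_cascade(calls, man, list(control_catalog = character(0),
                                      database_catalog = character(0)),
                     filter_config())
  expect_equal(nrow(res$accepted), 0L)
  expect_equal(res$rejected$reason, "replicate_discordant")
})
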