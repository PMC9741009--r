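sv_row <- function(type, chrom, start, end, support, caller = "caller1",
                   sample = "Aa", line = "A", chrom2 = NA_character_,
                   pos2 = NA_integer_) {
  data.frame(caller_id = caller, line_id = line, sample_id = sample,
             sv_type = type, chrom = chrom, start = as.integer(start),
             end = as.integer(end), chrom2 = chrom2,
             pos2 = as.integer(pos2),
             size = as.integer(end - start + 1L), support = as.integer(support),
             stringsAsFactors = FALSE)
}

test_that("support filter: strict >100 for translocations, caller minimums otherwise", {
  cfg <- sv_config(caller_min_support = c(lumpy = 10L))
  svs <- rbind(
    sv_row("CTX", "chr1", 100, 100, 101, chrom2 = "chr2", pos2 = 5000),
    sv_row("CTX", "chr1", 200, 200, 100, chrom2 = "chr2", pos2 = 6000),
    sv_row("ITX", "chr1", 300, 9000, 150),
    sv_row("DEL", "chr1", 400, 900, 49, caller = "breakdancer"),
    sv_row("DEL", "chr1", 400, 900, 50, caller = "breakdancer"),
    sv_row("DEL", "chr1", 500, 900, 12, caller = "lumpy"),
    sv_row("DEL", "chr1", 500, 900, 9, caller = "lumpy"))
  out <- support_filter(svs, cfg)
  expect_equal(out$support, c(101L, 150L, 50L, 12L))
  expect_equal(nrow(support_filter(svs[0, ], cfg)), 0L)
})

test_that("translocation merging follows the +/-2000 bp rule with single linkage", {
  cfg <- sv_config()
  a <- sv_row("ITX", "chr1", 100000, 150000, 120)
  b <- sv_row("ITX", "chr1", 101500, 150400, 200)
  merged <- merge_translocations(rbind(a, b), cfg)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$support, 200L)
  # support-weighted coordinates
  expect_equal(merged$start, as.integer(round((100000 * 120 + 101500 * 200) / 320)))
  # beyond tolerance: not merged
  c_ <- sv_row("ITX", "chr1", 102500, 150000, 120)
  expect_equal(nrow(merge_translocations(rbind(a, c_), cfg)), 2L)
  # chain A-B-C with A-C beyond tolerance still one cluster (single linkage)
  chain <- rbind(sv_row("ITX", "chr1", 100000, 150000, 100),
                 sv_row("ITX", "chr1", 101500, 150000, 100),
                 sv_row("ITX", "chr1", 103000, 150000, 100))
  expect_equal(nrow(merge_translocations(chain, cfg)), 1L)
  expect_error(merge_translocations(rbind(a, sv_row("CTX", "chr1", 1, 1, 200,
                                                    chrom2 = "chr2", pos2 = 10)),
                                    cfg), "single sv_type")
  expect_error(merge_translocations(sv_row("DEL", "chr1", 1, 500, 200), cfg),
               "ITX or CTX")
})

test_that("clustering matches the brute-force transitive-closure oracle and is order-independent", {
  set.seed(77)
  for (trial in 1:6) {
    n <- 25L
    svs <- do.call(rbind, lapply(seq_len(n), function(i)
      sv_row(sample(c("DEL", "DUP"), 1), sample(c("chr1", "chr2"), 1),
             s <- sample(1:80000, 1), s + sample(200:5000, 1),
             sample(50:300, 1))))
    got <- radmut:::sv_cluster_ids(svs, 2000L)
    want <- oracle_cluster(svs, 2000L)
    # same partition (ids may be permuted)
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(x) length(unique(x)) == 1L)))
    # permutation invariance of the induced partition
    perm <- sample(n)
    got_p <- radmut:::sv_cluster_ids(svs[perm, ], 2000L)
    expect_true(all(tapply(got_p, got[perm], function(x) length(unique(x)) == 1L)))
    expect_equal(length(unique(got_p)), length(unique(got)))
  }
})

test_that("consensus keeps multi-caller, both-replicate records and drops cross-line matches", {
  man <- two_line_manifest()
  cfg <- sv_config(min_callers = 2L)
  svs <- rbind(
    # true DEL in line A: 2 callers x 2 replicates, jittered
    sv_row("DEL", "chr1", 10000, 15000, 120, "caller1", "Aa"),
    sv_row("DEL", "chr1", 10300, 15200, 110, "caller2", "Aa"),
    sv_row("DEL", "chr1", 9900, 14900, 130, "caller1", "Ab"),
    sv_row("DEL", "chr1", 10100, 15100, 90, "caller2", "Ab"),
    # single-caller event: insufficient at min_callers = 2
    sv_row("DUP", "chr1", 40000, 42000, 100, "caller1", "Aa"),
    sv_row("DUP", "chr1", 40000, 42000, 100, "caller1", "Ab"),
    # single-replicate event: discordant
    sv_row("INV", "chr2", 5000, 8000, 100, "caller1", "Aa"),
    sv_row("INV", "chr2", 5000, 8000, 100, "caller2", "Aa"),
    # shared DEL in A and B: natural-variation candidate
    sv_row("DEL", "chr2", 30000, 33000, 100, "caller1", "Aa"),
    sv_row("DEL", "chr2", 30100, 33100, 100, "caller2", "Ab"),
    sv_row("DEL", "chr2", 30050, 33050, 100, "caller1", "Ba", line = "B"),
    sv_row("DEL", "chr2", 29950, 32950, 100, "caller2", "Bb", line = "B"))
  res <- sv_consensus(svs, man, cfg)
  expect_equal(nrow(res$records), 1L)
  expect_equal(res$records$sv_type, "DEL")
  expect_equal(res$records$line_id, "A")
  expect_lt(abs(res$records$start - 10000), 500)
  reasons <- res$removed$removed_reason
  expect_true("insufficient_callers" %in% reasons)
  expect_true("replicate_discordant" %in% reasons)
  expect_equal(sum(reasons == "shared_across_lines_or_control"), 2L)
  # report_only keeps the shared records but flags them
  res2 <- sv_consensus(svs, man, sv_config(min_callers = 2L,
                                           cross_line_filter = "report_only"))
  shared <- res2$records[res2$records$shared, ]
  expect_setequal(shared$line_id, c("A", "B"))
})

test_that("control-only SVs are removed everywhere under the strict filter", {
  man <- two_line_manifest()
  svs <- rbind(
    sv_row("DEL", "chr1", 20000, 24000, 100, "caller1", "Aa"),
    sv_row("DEL", "chr1", 20000, 24000, 100, "caller1", "Ab"),
    sv_row("DEL", "chr1", 20100, 24100, 100, "caller1", "c1", line = "C"))
  res <- sv_consensus(svs, man, sv_config())
  expect_equal(nrow(res$records), 0L)
  expect_true(all(res$removed$removed_reason == "shared_across_lines_or_control"))
})

test_that("bin depth scan calls homozygous deletion and duplication runs", {
  cfg <- sv_config()
  mk <- function(depths) data.frame(chrom = "chr1",
                                    bin_start = seq(1L, by = 1000L,
                                                    length.out = length(depths)),
                                    depth = depths)
  ctl <- mk(rep(30, 40))
  mut_d <- rep(30, 40); mut_d[11:20] <- 0        # 10 kb deletion
  mut_d[31:35] <- 62                             # 5 kb duplication
  out <- bin_depth_scan(mk(mut_d), ctl, 1000L, cfg)
  del <- out[out$sv_type == "DEL", ]
  expect_equal(nrow(del), 1L)
  expect_equal(del$size, 10000L)
  expect_equal(del$start, 10001L)
  dup <- out[out$sv_type == "DUP", ]
  expect_equal(dup$n_bins, 5L)
  # flat coverage: no candidates
  expect_equal(nrow(bin_depth_scan(ctl, ctl, 1000L, cfg)), 0L)
  expect_error(bin_depth_scan(mk(rep(30, 10)), ctl, 1000L, cfg), "structure")
})

test_that("depth scan recovers a homozygous truth deletion within one bin", {
  cfg <- tiny_config(seed = 91, chrom_length = 100000,
                     lines = list(line_spec("L1", "gamma", 150, 1, 0, 0,
                                            c("a", "b")),
                                  line_spec("C", "none", replicate_ids = "c1")))
  ref <- generate_reference(cfg)
  truth <- simulate_truth(cfg, ref)
  # plant a deterministic 5 kb deletion
  truth$svs <- data.frame(line_id = "L1", sv_type = "DEL", chrom = "chr1",
                          start = 40001L, end = 45000L, chrom2 = NA,
                          pos2 = NA, size = 5000L, sv_id = "tsv0001")
  bins <- simulate_depth_bins(truth, cfg, "L1", bin_size = 1000L)
  out <- bin_depth_scan(bins$mutant, bins$control, 1000L, sv_config())
  del <- out[out$sv_type == "DEL" & out$chrom == "chr1", ]
  expect_equal(nrow(del), 1L)
  expect_lte(abs(del$start - 40001L), 1000L)
  expect_lte(abs(del$end - 45000L), 1000L)
})

test_that("gene overlap labels genic vs intergenic and flags transposon genes", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(1000L, 20000L), end = c(5000L, 26000L),
                      annotation = c("protein_coding", "transposon"))
  svs <- rbind(sv_row("DEL", "chr1", 2000, 3000, 100),
               sv_row("DEL", "chr1", 8000, 9000, 100),
               sv_row("DEL", "chr1", 19000, 21000, 100),
               sv_row("CTX", "chr2", 100, 100, 150, chrom2 = "chr1", pos2 = 2500))
  out <- sv_gene_overlap(svs, genes)
  expect_equal(out$overlap_class, c("genic", "intergenic", "genic", "genic"))
  expect_equal(out$transposon_overlap, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$genes_hit[1], "g1")
  # percentage arithmetic over an overlap table: 126 of 340 intergenic
  expect_equal(round(100 * 126 / 340), 37)
})

test_that("translocation accounting: ITX/CTX also count as origin-locus deletions", {
  counts <- data.frame(snv = 100L, indel = 20L, del = 30L, dup = 4L,
                       inv = 2L, ins = 3L, itx = 2L, ctx = 5L)
  d <- derive_spectrum(counts, genome_size = 430e6)
  expect_equal(d$del_reported, 37L)
  expect_equal(d$n_sv, 37L + 4L + 2L + 3L)
  expect_equal(d$n_total, 120L + d$n_sv)
  d0 <- derive_spectrum(counts, 430e6, count_translocations_as_deletions = FALSE)
  expect_equal(d0$del_reported, 30L)
})
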