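# hand-built single-gene references on both strands for exact codon checks:
# plus-strand CDS ATG GAA TAA placed at a known offset
toy_reference <- function(strand = "+") {
  pad5 <- paste(rep("C", 30), collapse = "")
  pad3 <- paste(rep("G", 30), collapse = "")
  cds <- "ATGGAATAA"
  body <- if (strand == "+") cds else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  seqs <- Biostrings::DNAStringSet(setNames(paste0(pad5, body, pad3), "chr1"))
  structure(list(
    genome = seqs,
    genes = data.frame(gene_id = "g1", chrom = "chr1", strand = strand,
                       start = 31L, end = 39L, annotation = "protein_coding"),
    cds = data.frame(gene_id = "g1", chrom = "chr1", exon_rank = 1L,
                     start = 31L, end = 39L)), class = "radmut_reference")
}

test_that("coding SNVs classify by the genetic code on the plus strand", {
  ref <- toy_reference("+")
  # codon 2 GAA, first base G->T gives TAA: nonsense
  out <- classify_snv("chr1", 34L, "G", "T", ref)
  expect_equal(out$effect, "nonsense"); expect_equal(out$impact, "HIGH")
  # third base of codon 2, A->G: GAA->GAG both Glu: silent
  out <- classify_snv("chr1", 36L, "A", "G", ref)
  expect_equal(out$effect, "silent"); expect_equal(out$impact, "LOW")
  # GAA->GCA Glu->Ala: missense
  out <- classify_snv("chr1", 35L, "A", "C", ref)
  expect_equal(out$effect, "missense"); expect_equal(out$impact, "MODERATE")
  # start codon hit: ATG->CTG
  out <- classify_snv("chr1", 31L, "A", "C", ref)
  expect_equal(out$effect, "start_lost"); expect_equal(out$impact, "HIGH")
  # stop codon lost: TAA->CAA
  out <- classify_snv("chr1", 37L, "T", "C", ref)
  expect_equal(out$effect, "stop_lost"); expect_equal(out$impact, "HIGH")
  # reference mismatch is a hard error
  expect_error(classify_snv("chr1", 34L, "A", "T", ref), "mismatch")
})

test_that("the same biology classifies identically on the minus strand", {
  ref <- toy_reference("-")
  # genomic coordinates mirror: CDS runs 39 -> 31; codon-2 first base (G in
  # GAA) sits at genomic 36 as complement C; C->A makes TAA on coding strand
  out <- classify_snv("chr1", 36L, "C", "A", ref)
  expect_equal(out$effect, "nonsense")
  # third base of codon 2: genomic 34 complement T; T->C = silent GAA->GAG
  out <- classify_snv("chr1", 34L, "T", "C", ref)
  expect_equal(out$effect, "silent")
})

test_that("indels classify by frame, with in-frame stop gains upgraded to HIGH", {
  cfg <- tiny_config(seed = 71, n_genes = 6)
  ref <- generate_reference(cfg)
  ex <- ref$cds[ref$cds$end - ref$cds$start > 40, ][1, ]
  gene <- ref$genes[ref$genes$gene_id == ex$gene_id, ]
  pos <- ex$start + 15L
  base <- as.character(Biostrings::subseq(ref$genome[[gene$chrom]], pos, pos))
  # 2 bp deletion: frameshift
  del2 <- as.character(Biostrings::subseq(ref$genome[[gene$chrom]], pos, pos + 2L))
  out <- classify_indel(gene$chrom, pos, del2, base, ref)
  expect_equal(out$effect[out$gene_id == gene$gene_id], "frameshift")
  expect_equal(out$impact[out$gene_id == gene$gene_id], "HIGH")
  # 14 bp deletion (net -14, not a multiple of 3): frameshift
  del14 <- as.character(Biostrings::subseq(ref$genome[[gene$chrom]], pos, pos + 14L))
  out <- classify_indel(gene$chrom, pos, del14, base, ref)
  expect_equal(out$effect[out$gene_id == gene$gene_id], "frameshift")
  # 3 bp in-frame deletion: MODERATE unless a stop appears
  del3 <- as.character(Biostrings::subseq(ref$genome[[gene$chrom]], pos, pos + 3L))
  out <- classify_indel(gene$chrom, pos, del3, base, ref)
  expect_equal(out$effect[out$gene_id == gene$gene_id], "inframe_indel")
  want <- oracle_effect(ref, gene$gene_id, gene$chrom, pos, del3, base)
  expect_equal(out$impact[out$gene_id == gene$gene_id], want$impact)
})

test_that("non-coding variants map to MODIFIER with the right locality", {
  cfg <- tiny_config(seed = 72, n_genes = 4)
  ref <- generate_reference(cfg)
  # multi-exon gene -> has an intron
  multi <- names(which(table(ref$cds$gene_id) > 1))
  expect_gt(length(multi), 0)
  gid <- multi[1]
  ex <- ref$cds[ref$cds$gene_id == gid, ]
  ex <- ex[order(ex$start), ]
  gene <- ref$genes[ref$genes$gene_id == gid, ]
  intron_pos <- ex$end[1] + 10L
  base <- as.character(Biostrings::subseq(ref$genome[[gene$chrom]],
                                          intron_pos, intron_pos))
  out <- classify_snv(gene$chrom, intron_pos, base,
                      setdiff(c("A", "C", "G", "T"), base)[1], ref)
  expect_equal(out$effect[out$gene_id == gid], "intronic")
  expect_equal(out$impact[out$gene_id == gid], "MODIFIER")
  expect_false(out$splice_proximal[out$gene_id == gid])
  # first intron base: splice-proximal warning
  sp <- ex$end[1] + 1L
  base <- as.character(Biostrings::subseq(ref$genome[[gene$chrom]], sp, sp))
  out <- classify_snv(gene$chrom, sp, base,
                      setdiff(c("A", "C", "G", "T"), base)[1], ref)
  expect_true(out$splice_proximal[out$gene_id == gid])
  # far from any gene: intergenic
  far <- toy_reference("+")
  out <- classify_snv("chr1", 15L, "C", "A",
                      structure(list(genome = far$genome,
                                     genes = far$genes[0, ], cds = far$cds[0, ]),
                                class = "radmut_reference"))
  expect_equal(out$effect, "intergenic")
})

test_that("classifier agrees with the protein-diff oracle on random coding variants", {
  cfg <- tiny_config(seed = 73, n_genes = 10, chrom_length = 100000)
  ref <- generate_reference(cfg)
  vars <- random_coding_variants(ref, n = 250, seed = 74)
  ann <- annotate_variants(vars[, c("chrom", "pos", "ref", "alt")], ref)
  for (i in seq_len(nrow(vars))) {
    want <- oracle_effect(ref, vars$gene_id[i], vars$chrom[i], vars$pos[i],
                          vars$ref[i], vars$alt[i])
    got <- ann[ann$pos == vars$pos[i] & ann$gene_id == vars$gene_id[i] & ann$ref == vars$ref[i] &
               ann$alt == vars$alt[i], ]
    expect_equal(got$effect[1], want$effect,
                 label = paste("variant", vars$chrom[i], vars$pos[i],
                               vars$ref[i], ">", vars$alt[i]))
    expect_equal(got$impact[1], want$impact)
  }
})

test_that("effect percentages reproduce printed rows and sum to 100", {
  p <- effect_percentages(data.frame(missense = 131, nonsense = 1, silent = 83))
  expect_equal(p$pct_missense, 60.930)
  expect_equal(p$pct_nonsense, 0.465)
  expect_equal(p$pct_silent, 38.605)
  p2 <- effect_percentages(data.frame(missense = 100, nonsense = 4, silent = 97))
  expect_equal(p2$pct_missense, 49.751)
  expect_equal(p2$pct_nonsense, 1.990)
  expect_equal(p2$pct_silent, 48.259)
  p3 <- effect_percentages(data.frame(missense = 1, nonsense = 0, silent = 0))
  expect_equal(p3$pct_missense, 100)
  # zero denominator: NA, not an error
  p4 <- effect_percentages(data.frame(missense = 0, nonsense = 0, silent = 0))
  expect_true(is.na(p4$pct_missense))
  # random tables sum to 100 within rounding
  set.seed(9)
  for (i in 1:20) {
    x <- effect_percentages(data.frame(missense = sample(0:500, 1) + 1,
                                       nonsense = sample(0:50, 1),
                                       silent = sample(0:500, 1)))
    expect_lt(abs(x$pct_missense + x$pct_nonsense + x$pct_silent - 100), 0.01)
  }
})
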