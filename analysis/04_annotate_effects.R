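#!/usr/bin/env Rscript
# Classify the accepted small variants by predicted functional effect
# (codon-level, against the simulated reference and gene models) and the
# consensus SVs by gene overlap. Writes annotation tables and per-line
# effect/impact count tables under results/annotation/.

suppressMessages(library(radmut))

sim <- "results/simulated"
out <- "results/annotation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genome <- Biostrings::readDNAStringSet(file.path(sim, "reference.fa"))
names(genome) <- sub(" .*", "", names(genome))
accepted <- read.delim("results/filter/accepted_small_variants.tsv")
svs <- read.delim("results/sv/consensus_svs.tsv")

# rebuild the gene models deterministically from the simulation config
cfg_sim <- sim_config(seed = 20221125L)
reference <- generate_reference(cfg_sim)
stopifnot(identical(as.character(reference$genome), as.character(genome)))

ann <- annotate_variants(accepted, reference)
effects <- effect_count_table(ann)
sv_ann <- sv_gene_overlap(svs, reference$genes)

cat("Annotated", nrow(accepted), "small variants ->", nrow(ann),
    "variant-gene annotations\n")
cat("Effect classes:\n"); print(table(ann$effect))
cat("Impact tiers:\n"); print(table(ann$impact))
n_genic <- sum(sv_ann$overlap_class == "genic")
cat(sprintf("SV overlap: %d genic (%.0f%%), %d intergenic; %d hit transposon-annotated genes\n",
            n_genic, 100 * n_genic / max(1, nrow(sv_ann)),
            sum(sv_ann$overlap_class == "intergenic"),
            sum(sv_ann$transposon_overlap)))

write.table(ann, file.path(out, "small_variant_annotations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(effects, file.path(out, "effect_counts_per_line.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sv_ann, file.path(out, "sv_gene_overlap.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Tables written under", out, "\n")
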