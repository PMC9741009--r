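#' Generate a synthetic reference genome with gene models
#'
#' Produces random chromosome sequences and plants non-overlapping
#' protein-coding gene models on them. Every gene model satisfies the
#' contracts the effect annotator relies on: the spliced CDS starts with
#' ATG, ends with a stop codon, has length divisible by 3, and CDS exons of
#' one gene do not overlap. Genes may lie on either strand and have 1-3 CDS
#' exons separated by introns. A fraction of genes is annotated as
#' transposon-related so that SV overlap reports can exercise that flag.
#'
#' @param config a [sim_config()]
#' @return a `radmut_reference` list with elements `genome`
#'   ([Biostrings::DNAStringSet]), `genes` (data.frame: `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `annotation`) and `cds` (data.frame:
#'   `gene_id`, `exon_rank` in transcription order, `start`, `end` genomic
#'   1-based inclusive)
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "radmut_sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  bases <- c("A", "C", "G", "T")
  chroms <- paste0("chr", seq_len(config$n_chroms))
  seqs <- vapply(chroms, function(ch)
    paste(sample(bases, config$chrom_length, replace = TRUE), collapse = ""),
    character(1))

  genes <- list(); cds <- list()
  if (config$n_genes > 0) {
    per_chrom <- table(factor(rep_len(chroms, config$n_genes), levels = chroms))
    max_span <- 3 * 220 + 2 * 400 + 50  # generous upper bound on a gene span
    margin <- 1000L
    for (ch in chroms) {
      k <- as.integer(per_chrom[[ch]])
      if (k == 0) next
      slot <- (config$chrom_length - 2L * margin) %/% k
      if (slot < max_span + 200L)
        stop("chrom_length too small to place ", config$n_genes,
             " genes: need slots of at least ", max_span + 200L,
             " bp, have ", slot)
      for (g in seq_len(k)) {
        gene_id <- sprintf("G%s_%02d", sub("chr", "", ch), g)
        strand <- sample(c("+", "-"), 1L)
        n_exons <- sample(1:3, 1L)
        n_codons <- sample(60:180, 1L)
        # split codons across exons, each exon >= 5 codons
        cuts <- if (n_exons > 1) sort(sample(5:(n_codons - 5), n_exons - 1L)) else integer(0)
        exon_codons <- diff(c(0L, cuts, n_codons))
        if (any(exon_codons < 2)) { exon_codons <- rep(n_codons %/% n_exons, n_exons)
                                    exon_codons[1] <- n_codons - sum(exon_codons[-1]) }
        exon_len <- 3L * exon_codons
        intron_len <- if (n_exons > 1) sample(80:400, n_exons - 1L, replace = TRUE) else integer(0)
        spliced <- build_cds_sequence(n_codons)
        gstart <- margin + (g - 1L) * slot + sample(0:150, 1L)
        # genomic exon lengths ascending; transcription order follows strand
        glen <- if (strand == "+") exon_len else rev(exon_len)
        starts <- gstart + c(0L, cumsum(glen[-n_exons] + intron_len))
        ends <- starts + glen - 1L
        # assign spliced chunks to genomic exons
        chunk_ends <- cumsum(exon_len)
        chunk_starts <- chunk_ends - exon_len + 1L
        for (j in seq_len(n_exons)) {
          rank <- if (strand == "+") j else n_exons - j + 1L
          chunk <- substr(spliced, chunk_starts[rank], chunk_ends[rank])
          if (strand == "-")
            chunk <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(chunk)))
          substr(seqs[[ch]], starts[j], ends[j]) <- chunk
        }
        ranks <- if (strand == "+") seq_len(n_exons) else rev(seq_len(n_exons))
        cds[[length(cds) + 1L]] <- data.frame(
          gene_id = gene_id, exon_rank = ranks, start = starts, end = ends,
          stringsAsFactors = FALSE)
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gene_id, chrom = ch, strand = strand,
          start = gstart, end = max(ends),
          annotation = if (runif(1) < 0.1) "transposon" else "protein_coding",
          stringsAsFactors = FALSE)
      }
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(), chrom = character(), strand = character(),
               start = integer(), end = integer(), annotation = character())
  cds_df <- if (length(cds)) {
    out <- do.call(rbind, cds)
    out$chrom <- genes$chrom[match(out$gene_id, genes$gene_id)]
    out[, c("gene_id", "chrom", "exon_rank", "start", "end")]
  } else data.frame(gene_id = character(), chrom = character(),
                    exon_rank = integer(), start = integer(), end = integer())
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms
  structure(list(genome = genome, genes = genes, cds = cds_df),
            class = "radmut_reference")
}

# random CDS: ATG + non-stop codons + one stop codon
build_cds_sequence <- function(n_codons) {
  stopifnot(n_codons >= 3)
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  mid <- character(n_codons - 2L)
  for (i in seq_along(mid)) {
    repeat {
      cod <- paste(sample(bases, 3L, replace = TRUE), collapse = "")
      if (!cod %in% stops) break
    }
    mid[i] <- cod
  }
  paste0("ATG", paste(mid, collapse = ""), sample(stops, 1L))
}

#' Spliced CDS sequence of a gene model
#'
#' Concatenates the CDS exons in transcription order; minus-strand exons
#' are reverse-complemented so the result reads 5'->3' on the coding
#' strand.
#'
#' @param reference a `radmut_reference`
#' @param gene_id gene label
#' @return character scalar, the coding sequence
#' @export
spliced_cds <- function(reference, gene_id) {
  gene <- reference$genes[reference$genes$gene_id == gene_id, ]
  if (nrow(gene) != 1L) stop("unknown gene_id: ", gene_id)
  ex <- reference$cds[reference$cds$gene_id == gene_id, ]
  ex <- ex[order(ex$exon_rank), ]
  chromseq <- reference$genome[[gene$chrom]]
  chunks <- vapply(seq_len(nrow(ex)), function(i) {
    s <- as.character(Biostrings::subseq(chromseq, ex$start[i], ex$end[i]))
    if (gene$strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1))
  paste(chunks, collapse = "")
}

#' Write reference FASTA and gene-model GFF3
#'
#' @param reference a `radmut_reference`
#' @param dir output directory (created if missing)
#' @return invisibly, the paths written (`fasta`, `gff3`)
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "reference.fa")
  gff3 <- file.path(dir, "genes.gff3")
  Biostrings::writeXStringSet(reference$genome, fasta)
  write_gff3(reference, gff3)
  invisible(list(fasta = fasta, gff3 = gff3))
}

# minimal deterministic GFF3 writer: gene, mRNA and CDS features with
# correct phase in transcription order
write_gff3 <- function(reference, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ch in names(reference$genome))
    writeLines(sprintf("##sequence-region %s 1 %d", ch,
                       Biostrings::width(reference$genome[ch])), con)
  g <- reference$genes
  if (nrow(g) == 0) return(invisible(path))
  g <- g[order(g$chrom, g$start), ]
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    writeLines(sprintf("%s\tradmut\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Note=%s",
                       g$chrom[i], g$start[i], g$end[i], g$strand[i], gid,
                       g$annotation[i]), con)
    writeLines(sprintf("%s\tradmut\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
                       g$chrom[i], g$start[i], g$end[i], g$strand[i], gid, gid), con)
    ex <- reference$cds[reference$cds$gene_id == gid, ]
    ex <- ex[order(ex$exon_rank), ]
    phase <- (3L - (cumsum(c(0L, ex$end - ex$start + 1L)) %% 3L)) %% 3L
    ex <- ex[order(ex$start), ]  # GFF rows in genomic order
    for (j in seq_len(nrow(ex))) {
      ph <- phase[ex$exon_rank[j]]
      writeLines(sprintf("%s\tradmut\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.1.cds%d;Parent=%s.1",
                         g$chrom[i], ex$start[j], ex$end[j], g$strand[i], ph,
                         gid, ex$exon_rank[j], gid), con)
    }
  }
  invisible(path)
}
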