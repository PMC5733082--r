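#!/usr/bin/env Rscript
# Stage 5 — genomic distribution of the changed loci: plant a synthetic set
# of gene models over the simulated genome (the study's real fragments were
# mapped to the rat genome, which has no stand-in here), assign every
# scored locus to a feature class, and tabulate hyper / hypo / unchanged
# loci per chromosome and per feature.

source("analysis/00_config.R")
cfg <- run_config

cohort <- readRDS(file.path(SCRATCH, "cohort.rds"))
scored <- readRDS(file.path(SCRATCH, "scored.rds"))
truth <- utils::read.delim(file.path(SCRATCH, "truth_band_types.tsv"))

# synthetic gene models: ~40 genes of 2-6 kb with 2-5 exons, random strand
set.seed(cfg$seed + 7)
gff <- file.path(SCRATCH, "synthetic_genes.gff3")
lines <- "##gff-version 3"
gid <- 0
for (ch in names(cohort$genotypes$WT$genome$seq)) {
  L <- nchar(cohort$genotypes$WT$genome$seq[[ch]])
  starts <- sort(sample.int(L - 8000, 20))
  for (s in starts) {
    gid <- gid + 1
    glen <- sample(2000:6000, 1)
    strand <- sample(c("+", "-"), 1)
    id <- sprintf("gene%03d", gid)
    lines <- c(lines, sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              ch, s, s + glen - 1, strand, id))
    n_ex <- sample(2:5, 1)
    bounds <- sort(sample(seq(s, s + glen - 200, by = 50), n_ex))
    for (b in bounds)
      lines <- c(lines, sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                                ch, b, min(b + 180, s + glen - 1), strand, id))
  }
}
writeLines(lines, gff)
index <- load_gene_models(gff, promoter_width = 2000)
message(sprintf("synthetic gene models: %d genes, %d exons",
                length(index$genes), length(index$exons)))

# label every strict-consensus locus with its methylation verdict
strict <- replicate_consensus(scored$matrix, "strict_identical")
partition <- partition_inheritance(compare_to_wildtype(strict))
labels <- partition$loci[, c("locus", "methylation_variation")]
unchanged <- setdiff(truth$locus, labels$locus)
labels <- rbind(labels, data.frame(locus = unchanged,
                                   methylation_variation = "unchanged"))

assignments <- assign_feature(truth[, c("locus", "chrom", "start", "end")],
                              index)
dist <- distribution_summary(assignments, labels)
print(dist$by_feature)
print(dist$by_chromosome)
write_tsv(cbind(feature = rownames(dist$by_feature), dist$by_feature),
          "feature_distribution.tsv")
write_tsv(cbind(chrom = rownames(dist$by_chromosome), dist$by_chromosome),
          "chromosome_distribution.tsv")
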