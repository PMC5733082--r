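#!/usr/bin/env Rscript
# Stage 1 — simulate the cohort: genomes, methylomes, planted genotype
# effects with their sharing structure, and noisy replicate peak tables.

source("analysis/00_config.R")
cfg <- run_config

genome <- generate_genome(cfg$n_chrom, cfg$chrom_length, cfg$ccgg_per_kb,
                          cfg$ecori_per_kb, cfg$nested_fraction,
                          seed = cfg$seed)
print(genome)
methylome <- generate_methylome(genome, cfg$meth_fraction, seed = cfg$seed + 1)
cohort <- apply_genotype_effects(genome, methylome, cfg$effects,
                                 seed = cfg$seed + 2)
message(sprintf("planted %d events: %s", nrow(cohort$events),
                paste(sprintf("%s=%d", names(table(cohort$events$type)),
                              table(cohort$events$type)), collapse = ", ")))
message(sprintf("sharing: %s",
                paste(sprintf("%s=%d", names(table(cohort$events$scope)),
                              table(cohort$events$scope)), collapse = ", ")))

truth <- truth_band_types(cohort, cfg$primers, cfg$size_range)
message(sprintf("locus universe (noise-free truth): %d loci", nrow(truth)))

peaks <- emit_peak_tables(cohort, cfg$primers, cfg$replicates, cfg$noise,
                          seed = cfg$seed + 3, size_window = cfg$size_range)
message(sprintf("emitted %d peaks over %d samples x 2 lanes",
                nrow(peaks), cfg$replicates * 3))

write_genome_fasta(genome, file.path(SCRATCH, "base_genome.fasta"))
write_methylome_tsv(methylome, file.path(SCRATCH, "base_methylome.tsv"))
write_events_tsv(cohort, file.path(SCRATCH, "planted_events.tsv"))
write_tsv(truth, "truth_band_types.tsv", SCRATCH)
write_peak_table(peaks, file.path(SCRATCH, "peaks.csv"))
saveRDS(cohort, file.path(SCRATCH, "cohort.rds"))
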