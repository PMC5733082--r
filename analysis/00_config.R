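# Shared configuration for the analysis workflow.
#
# One simulated cohort stands in for the rat sperm study: 3 genotypes
# (wild type, transgene-negative and transgene-positive offspring) x 3
# biological replicates x 2 digestion lanes, scored over the 64 selective
# primer-pair combinations. The genome size is chosen to give a locus
# universe of a few thousand bins; peak emission uses a realistic noise
# model (5% dropout, 2 spurious peaks per lane, 0.15 bp sizing jitter,
# log-normal heights straddling nothing: median 5000 RFU, sdlog 0.6 so a
# small tail falls under the 1000 RFU filter).

library(epimsap)

RUN_SEED <- 20171212
SCRATCH <- "scratch/msap_run"
RESULTS <- "results/analysis"

dir.create(SCRATCH, recursive = TRUE, showWarnings = FALSE)
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

run_config <- msap_config(
  n_chrom = 2,
  chrom_length = 200000,
  ccgg_per_kb = 2,
  ecori_per_kb = 2,
  nested_fraction = 0.2,
  meth_fraction = 0.55,
  effects = genotype_effect_config(),   # defaults mirror the study's DAL load
  primers = primer_panel(1, 2),         # 4 x 16 = 64 selective combinations
  replicates = 3,
  noise = msap_noise(dropout_prob = 0.05, spurious_rate = 2,
                     size_jitter_sd = 0.15, height_meanlog = log(5000),
                     height_sdlog = 0.6),
  seed = RUN_SEED
)

write_tsv <- function(x, name, dir = RESULTS) {
  path <- file.path(dir, name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}
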