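#!/usr/bin/env Rscript
# Stage 4 — BSP cross-validation: simulate 10 sequenced clones per genotype
# at planted methylation-event loci and check that the clone-level calls
# agree with the MSAP hyper/hypo direction.

source("analysis/00_config.R")
cfg <- run_config

cohort <- readRDS(file.path(SCRATCH, "cohort.rds"))
ev <- cohort$events[cohort$events$type %in% c("hyper", "hypo"), ]
ev <- head(ev[order(ev$event_id), ], 20)  # validate a sample of 20 loci
wt <- cohort$genotypes$WT

rows <- lapply(seq_len(nrow(ev)), function(i) {
  e <- ev[i, ]
  carrier <- if (e$scope == "pos_only") "POS" else "NEG"
  cg <- cohort$genotypes[[carrier]]
  start <- max(0, e$pos - 100)
  end <- e$pos + 104
  b_wt <- simulate_bsp_clones(wt$genome, wt$methylome, e$chrom, start, end,
                              n_clones = 10, seed = cfg$seed + 100 + i)
  b_mu <- simulate_bsp_clones(cg$genome, cg$methylome, e$chrom, start, end,
                              n_clones = 10, seed = cfg$seed + 200 + i)
  p <- e$pos + 1 - start + 1
  f_wt <- b_wt$calls$fraction[b_wt$calls$position == p]
  f_mu <- b_mu$calls$fraction[b_mu$calls$position == p]
  dir <- if (e$type == "hyper") "hypermethylation" else "hypomethylation"
  data.frame(event_id = e$event_id, type = e$type, scope = e$scope,
             carrier = carrier, chrom = e$chrom, pos = e$pos,
             wt_fraction = f_wt, carrier_fraction = f_mu,
             delta = f_mu - f_wt,
             verdict = concordance(dir, f_mu - f_wt))
})
conc <- do.call(rbind, rows)
print(conc)
message(sprintf("MSAP/BSP concordance: %d/%d loci concordant",
                sum(conc$verdict == "concordant"), nrow(conc)))
write_tsv(conc, "bsp_concordance.tsv")
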