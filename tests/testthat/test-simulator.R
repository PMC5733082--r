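test_that("generated genomes meet the requested site densities and index their motifs", {
  g <- generate_genome(2, 15000, ccgg_per_kb = 2, ecori_per_kb = 2,
                       nested_fraction = 0.3, seed = 11)
  expect_gte(nrow(g$ccgg), 2 * 2 * 15)
  expect_gte(nrow(g$ecori), 2 * 2 * 15)
  for (i in seq_len(nrow(g$ecori)))
    expect_equal(substr(g$seq[[g$ecori$chrom[i]]], g$ecori$start[i] + 1,
                        g$ecori$start[i] + 6), "GAATTC")
  for (i in seq_len(nrow(g$ccgg)))
    expect_equal(substr(g$seq[[g$ccgg$chrom[i]]], g$ccgg$start[i] + 1,
                        g$ccgg$start[i] + 4), "CCGG")
  # and no motif occurrences beyond the planted tables (naive rescan)
  for (ch in names(g$seq)) {
    expect_equal(oracle_scan(g$seq[[ch]], "GAATTC"),
                 sort(g$ecori$start[g$ecori$chrom == ch]))
    expect_equal(oracle_scan(g$seq[[ch]], "CCGG"),
                 sort(g$ccgg$start[g$ccgg$chrom == ch]))
  }
})

test_that("genome generation is deterministic and rejects impossible densities", {
  expect_identical(generate_genome(1, 10000, seed = 3),
                   generate_genome(1, 10000, seed = 3))
  expect_error(generate_genome(1, 100), "1 kb")
  expect_error(generate_genome(1, 1000, ccgg_per_kb = 50), "density")
})

test_that("digestion follows the isoschizomer rules", {
  g <- nested_pair_genome()
  m <- nested_methylome("internal_methylated", "unmethylated")
  msp <- digest(g, m, "MspI")
  hpa <- digest(g, m, "HpaII")
  eco <- digest(g, m, "EcoRI")
  expect_equal(sort(msp$cut), c(97, 161))        # MspI cuts regardless
  expect_equal(hpa$cut, 161)                     # HpaII blocked at CmCGG
  expect_equal(sort(eco$cut), g$ecori$start + 1)
  expect_error(digest(g, m[-1, ], "MspI"), "cover")
})

test_that("HpaII cut set is a subset of MspI's for random methylomes", {
  g <- generate_genome(1, 10000, seed = 5)
  for (s in 1:8) {
    m <- generate_methylome(g, meth_fraction = runif(1), seed = s)
    msp <- digest(g, m, "MspI")$cut
    hpa <- digest(g, m, "HpaII")$cut
    expect_true(all(hpa %in% msp))
  }
})

test_that("the four nested-pair methylation patterns produce the expected band types", {
  g <- nested_pair_genome()
  e1 <- g$ecori$start[1]
  size_S <- g$ccgg$start[1] - e1   # EcoRI cut to internal CCGG cut
  size_L <- g$ccgg$start[2] - e1   # EcoRI cut to external CCGG cut
  patterns <- list(
    a = c("unmethylated", "unmethylated"),
    b = c("internal_methylated", "unmethylated"),
    c = c("unmethylated", "internal_methylated"),
    d = c("internal_methylated", "internal_methylated"))
  type_of <- function(fr, size) {
    as.character(code_band_type(
      any(fr$lane == "EcoRI+MspI" & fr$size_bp == size),
      any(fr$lane == "EcoRI+HpaII" & fr$size_bp == size)))
  }
  got_L <- got_S <- character(0)
  for (p in names(patterns)) {
    fr <- msap_fragments(g, nested_methylome(patterns[[p]][1], patterns[[p]][2]))
    got_L[p] <- type_of(fr, size_L)
    got_S[p] <- type_of(fr, size_S)
  }
  # the long fragment scores III only when the internal site alone is
  # methylated; it is IV in every other pattern
  expect_equal(got_L, c(a = "IV", b = "III", c = "IV", d = "IV"))
  expect_equal(got_S, c(a = "I", b = "II", c = "I", d = "II"))
})

test_that("amplicon enumeration matches the brute-force oracle on small genomes", {
  for (s in 1:3) {
    g <- generate_genome(1, 15000, nested_fraction = 0.3, seed = s + 20)
    m <- generate_methylome(g, 0.5, seed = s)
    ce <- digest(g, m, "EcoRI")
    for (enz in c("MspI", "HpaII")) {
      chm <- digest(g, m, enz)
      for (suf in list(c("", ""), c("A", "GT"))) {
        primers <- data.frame(primer_pair = "P", e_suffix = suf[1],
                              hm_suffix = suf[2])
        got <- enumerate_amplicons(g, ce, chm, primers)
        want <- oracle_amplicons(g$seq[[1]], m, enz, suf[1], suf[2])
        got <- got[order(got$start), ]
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
        expect_equal(got$size_bp, want$size)
      }
    }
  }
})

test_that("loci never score type III when the genome has no nested pairs", {
  g <- generate_genome(1, 30000, nested_fraction = 0, seed = 9)
  m <- generate_methylome(g, 0.5, seed = 10)
  co <- apply_genotype_effects(g, m, genotype_effect_config(
    hyper_rate = 0.1, hypo_rate = 0.1, gain_rate = 0, loss_rate = 0),
    seed = 11)
  tr <- truth_band_types(co)
  expect_false(any(tr$WT == "III" | tr$NEG == "III" | tr$POS == "III"))
})

test_that("genotype effects honour rates, sharing and eligibility", {
  g <- generate_genome(1, 30000, seed = 31)
  m <- generate_methylome(g, 0.5, seed = 32)
  # all rates zero: offspring identical to wild type
  co0 <- apply_genotype_effects(g, m, genotype_effect_config(0, 0, 0, 0),
                                seed = 33)
  expect_equal(nrow(co0$events), 0)
  expect_identical(co0$genotypes$NEG, co0$genotypes$WT)
  expect_identical(co0$genotypes$POS, co0$genotypes$WT)
  # sharing fraction 1: every event lands in both offspring genotypes
  co1 <- apply_genotype_effects(g, m, genotype_effect_config(
    shared_fraction = 1), seed = 34)
  expect_true(all(co1$events$scope == "both"))
  expect_identical(co1$genotypes$NEG$methylome, co1$genotypes$POS$methylome)
  # hyper events flip unmethylated sites to methylated in carriers
  hy <- co1$events[co1$events$type == "hyper", ]
  key <- paste(hy$chrom, hy$pos)
  expect_true(all(m$status[match(key, paste(m$chrom, m$pos))] == "unmethylated"))
  mm <- co1$genotypes$NEG$methylome
  expect_true(all(mm$status[match(key, paste(mm$chrom, mm$pos))] ==
                    "internal_methylated"))
  expect_error(genotype_effect_config(hyper_rate = 1.2), "\\[0, 1\\]")
})

test_that("noise-free emission reproduces fragment presence exactly and deterministically", {
  co <- small_cohort(seed = 41, kb = 20)
  pk1 <- emit_peak_tables(co, replicates = 3, seed = 6)
  pk2 <- emit_peak_tables(co, replicates = 3, seed = 6)
  expect_identical(pk1, pk2)
  fr <- msap_fragments(co$genotypes$WT$genome, co$genotypes$WT$methylome)
  sub <- pk1[pk1$sample == "WT_R1", ]
  expect_equal(nrow(sub), nrow(fr))
  expect_setequal(paste(sub$lane, sub$size_bp), paste(fr$lane, fr$size_bp))
  expect_true(all(pk1$height > 1000))
})

test_that("2-of-3 consensus beats a single replicate under dropout (Monte-Carlo vs binomial)", {
  p <- 0.3
  set.seed(99)
  n_trials <- 4000
  # a locus truly present in one lane; per replicate it drops with prob p
  present <- matrix(runif(3 * n_trials) >= p, nrow = 3)
  single_miss <- mean(!present[1, ])
  consensus_miss <- mean(colSums(present) < 2)
  expect_lt(consensus_miss, single_miss)
  # closed form: P(>=2 of 3 dropouts) = 3p^2(1-p) + p^3
  expect_equal(consensus_miss, 3 * p^2 * (1 - p) + p^3, tolerance = 0.05)
})
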