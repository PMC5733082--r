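test_that("per-sample tallies reproduce the published count table arithmetic", {
  bc <- msap_reference_table("band_counts")
  mat <- matrix_from_counts(bc)
  tab <- tabulate_band_types(mat)
  expect_true(all(tab$total == 5438))
  key <- paste(tab$genotype, tab$replicate)
  want <- c("WT 1" = 52.70, "WT 2" = 53.38, "WT 3" = 52.07,
            "NEG 1" = 64.04, "NEG 2" = 64.22, "NEG 3" = 62.60,
            "POS 1" = 65.39, "POS 2" = 65.31, "POS 3" = 62.50)
  expect_equal(tab$methylation_pct[match(names(want), key)], unname(want))
  expect_equal(tab$unmethylation_pct, round_half_up(100 - tab$methylation_pct, 2))
  # genotype means of the per-replicate ratios
  expect_equal(round_half_up(mean(tab$methylation_pct[tab$genotype == "NEG"]), 2), 63.62)
  expect_equal(round_half_up(mean(tab$methylation_pct[tab$genotype == "POS"]), 2), 64.40)
})

test_that("an all-IV sample propagates the undefined-ratio error", {
  bad <- data.frame(genotype = "WT", replicate = 1,
                    n_I = 0, n_II = 0, n_III = 0, n_IV = 20)
  expect_error(tabulate_band_types(matrix_from_counts(bad)), "undefined")
})

mk_consensus <- function(wt, neg, pos) {
  df <- data.frame(locus = sprintf("L%d", seq_along(wt)),
                   genotype = rep(c("WT", "NEG", "POS"), each = length(wt)),
                   band_type = c(wt, neg, pos))
  class(df) <- c("msap_consensus", "data.frame")
  df
}

test_that("wild-type comparison flags DALs and partitions them by sharing", {
  cons <- mk_consensus(wt = c("I", "I", "II", "I", "II"),
                       neg = c("I", "II", "II", "II", "III"),
                       pos = c("I", "II", "I", "III", "II"))
  cmp <- compare_to_wildtype(cons)
  expect_equal(cmp$changed, c(FALSE, TRUE, TRUE, TRUE, TRUE))
  pt <- partition_inheritance(cmp)
  lab <- pt$loci$partition[match(c("L2", "L3", "L4", "L5"), pt$loci$locus)]
  expect_equal(lab, c("both", "only_positive", "inconsistent", "only_negative"))
  expect_equal(pt$n_unchanged + pt$n_dal, 5)
  expect_equal(pt$n_inconsistent, 1)
  # the Table-3-shaped summary column totals exclude inconsistent loci
  tot <- pt$summary[pt$summary$from_type == "Total", ]
  expect_equal(tot$only_negative + tot$only_positive + tot$both, 3)
})

test_that("consensus-excluded loci are dropped before comparison", {
  cons <- mk_consensus(wt = c("I", NA), neg = c("II", "I"), pos = c("II", "I"))
  cmp <- compare_to_wildtype(cons)
  expect_equal(nrow(cmp), 1)
  expect_equal(attr(cmp, "n_excluded"), 1)
})

test_that("the published transition counts reproduce every printed tally and fraction", {
  counts <- msap_reference_table("dal_transitions")
  cons <- expand_transition_counts(counts, n_total = 5438)
  cmp <- compare_to_wildtype(cons)
  pt <- partition_inheritance(cmp)
  tot <- pt$summary[pt$summary$from_type == "Total", ]
  expect_equal(tot$only_negative, 427)
  expect_equal(tot$only_positive, 449)
  expect_equal(tot$both, 647)
  expect_equal(pt$n_dal, 1523)
  dm <- count_dml(pt, n_total = 5438)
  expect_equal(dm$dml_total, 1042)
  cn <- dm$counts
  expect_equal(cn$hypermethylation[cn$partition == "both"], 268)
  expect_equal(cn$hypomethylation[cn$partition == "both"], 189)
  expect_equal(cn$hypermethylation[cn$partition == "only_positive"], 176)
  expect_equal(cn$hypomethylation[cn$partition == "only_positive"], 140)
  expect_equal(cn$hypermethylation[cn$partition == "only_negative"], 140)
  expect_equal(cn$hypomethylation[cn$partition == "only_negative"], 129)
  fr <- dm$fractions
  pct <- function(metric) fr$percent[fr$metric == metric]
  expect_equal(pct("DML / DAL"), 68.42)
  expect_equal(pct("hypermethylated shared DML / shared DAL"), 41.42)
  expect_equal(pct("hypomethylated shared DML / shared DAL"), 29.21)
  expect_equal(pct("inheritable DML / all DML"), 43.86)
  expect_equal(pct("unchanged loci / all loci"), 71.99)
  # round-trip: the summary table equals the input counts
  got <- pt$summary[pt$summary$from_type != "Total",
                    c("from_type", "to_type", "only_negative",
                      "only_positive", "both")]
  expect_equal(got, counts, ignore_attr = TRUE)
})

test_that("DAL/DML tallies conserve their denominators", {
  co <- small_cohort(seed = 71, kb = 30)
  pk <- emit_peak_tables(co, replicates = 3, seed = 72)
  sc <- score_peak_table(pk)
  cmp <- compare_to_wildtype(replicate_consensus(sc$matrix, "strict_identical"))
  pt <- partition_inheritance(cmp)
  dm <- count_dml(pt, n_total = nrow(cmp))
  expect_equal(pt$n_unchanged + pt$n_dal, nrow(cmp))
  cn <- dm$counts
  consistent <- sum(cn$hypermethylation + cn$hypomethylation + cn$unchanged)
  expect_equal(consistent + pt$n_inconsistent, pt$n_dal)
})

test_that("ratio t-tests find the published wild-type vs offspring difference", {
  ratios <- data.frame(
    genotype = rep(c("WT", "NEG", "POS"), each = 3),
    methylation_pct = c(52.70, 53.38, 52.07, 64.04, 64.22, 62.60,
                        65.39, 65.31, 62.50))
  tt <- compare_ratio_means(ratios)
  row <- tt[tt$group1 == "WT" & tt$group2 == "NEG", ]
  expect_true(row$significant)
  expect_lt(row$p_value, 0.05)
  # label swap symmetry
  swapped <- ratios
  swapped$genotype <- sub("^NEG$", "TMP", swapped$genotype)
  swapped$genotype <- sub("^WT$", "NEG", swapped$genotype)
  swapped$genotype <- sub("^TMP$", "WT", swapped$genotype)
  tt2 <- compare_ratio_means(swapped)
  expect_equal(tt2$p_value[tt2$group1 == "NEG" & tt2$group2 == "WT"],
               row$p_value)
  # identical groups give statistic 0, p = 1
  same <- data.frame(genotype = rep(c("A", "B"), each = 3),
                     methylation_pct = rep(c(50, 51, 52), 2))
  tts <- compare_ratio_means(same)
  expect_equal(tts$t, 0)
  expect_equal(tts$p_value, 1)
  expect_error(compare_ratio_means(data.frame(
    genotype = c("A", "B", "B"), methylation_pct = c(1, 2, 3))), "replicates")
})
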