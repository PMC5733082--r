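mk_peaks <- function(size, height, sample = "WT_R1", genotype = "WT",
                     replicate = 1, lane = "EcoRI+MspI", primer = "P") {
  data.frame(sample = sample, genotype = genotype, replicate = replicate,
             lane = lane, primer_pair = primer, size_bp = size,
             height = height)
}

test_that("peak filtering applies the strict height and size rules", {
  pk <- mk_peaks(size = c(49.9, 120, 120, 500, 250, 80),
                 height = c(5000, 1000, 1001, 2000, 3000, 999))
  out <- filter_peaks(pk)
  expect_equal(nrow(out), 2)            # only (120,1001) and (250,3000)
  expect_setequal(out$size_bp, c(120, 250))
  lg <- attr(out, "filter_log")
  expect_equal(unname(lg["input"]), 6)
  expect_equal(unname(lg["kept"]), 2)
  # idempotent
  again <- filter_peaks(out)
  expect_equal(as.data.frame(again), as.data.frame(out), ignore_attr = TRUE)
})

test_that("binning separates distant sizes and chains close ones", {
  pk <- mk_peaks(size = c(100.1, 100.3, 250.0), height = 5000)
  expect_equal(nrow(bin_loci(pk, 0.5)$bins), 2)
  # chained: consecutive gaps 0.4 <= tol, total width 0.8 <= 2*tol
  pk2 <- mk_peaks(size = c(100.0, 100.4, 100.8), height = 5000)
  expect_equal(nrow(bin_loci(pk2, 0.5)$bins), 1)
  # over-wide chains are split at the largest internal gap
  pk3 <- mk_peaks(size = c(100.0, 100.4, 100.9, 101.3), height = 5000)
  expect_equal(nrow(bin_loci(pk3, 0.5)$bins), 2)
  expect_equal(nrow(bin_loci(pk2[0, ], 0.5)$bins), 0)
})

test_that("binning matches a naive single-linkage oracle and ignores input order", {
  set.seed(17)
  for (rep in 1:5) {
    centers <- sort(runif(6, 60, 400))
    centers <- centers[c(TRUE, diff(centers) > 3)]  # well-separated
    sizes <- unlist(lapply(centers, function(c) c + runif(3, -0.2, 0.2)))
    pk <- mk_peaks(size = sizes, height = 5000)
    got <- bin_loci(pk, 0.5)
    want_lab <- oracle_single_linkage(sizes, 0.5)
    expect_equal(nrow(got$bins), length(unique(want_lab)))
    # same partition of peaks
    expect_equal(as.integer(factor(got$peaks$locus, levels = unique(got$peaks$locus))),
                 as.integer(factor(want_lab, levels = unique(want_lab))))
    # permutation invariance of the bin set
    perm <- sample(seq_along(sizes))
    got2 <- bin_loci(pk[perm, ], 0.5)
    expect_setequal(got$bins$locus, got2$bins$locus)
  }
})

test_that("samples code from lane presence, with IV for absence from both lanes", {
  pk <- rbind(
    mk_peaks(100, 5000, lane = "EcoRI+MspI"),    # M only -> II
    mk_peaks(200, 5000, lane = "EcoRI+MspI"),
    mk_peaks(200, 5000, lane = "EcoRI+HpaII"),   # both -> I
    mk_peaks(300, 5000, lane = "EcoRI+HpaII"),   # H only -> III
    mk_peaks(100, 5000, sample = "WT_R2", replicate = 2, lane = "EcoRI+MspI"),
    mk_peaks(100, 5000, sample = "WT_R2", replicate = 2, lane = "EcoRI+HpaII"))
  mat <- code_samples(bin_loci(pk, 0.5), lane_inventory = pk)
  w <- band_matrix(mat)
  r1 <- w$WT_R1[match(c("P@100.0", "P@200.0", "P@300.0"), w$locus)]
  expect_equal(r1, c("II", "I", "III"))
  # locus 200 and 300 unseen in WT_R2 -> IV
  r2 <- w$WT_R2[match(c("P@200.0", "P@300.0"), w$locus)]
  expect_equal(r2, c("IV", "IV"))
})

test_that("a sample missing one lane is a named error", {
  pk <- mk_peaks(100, 5000, lane = "EcoRI+MspI")
  expect_error(code_samples(bin_loci(pk, 0.5)), "WT_R1.*EcoRI\\+HpaII")
})

test_that("replicate consensus: majority keeps 2-of-3, strict demands unanimity", {
  counts <- data.frame(genotype = "WT", replicate = 1:3,
                       n_I = 0, n_II = 0, n_III = 0, n_IV = 0)
  mk_mat <- function(types) {
    df <- data.frame(locus = "L1", sample = paste0("WT_R", 1:3),
                     genotype = "WT", replicate = 1:3, band_type = types)
    class(df) <- c("msap_matrix", "data.frame")
    df
  }
  expect_equal(replicate_consensus(mk_mat(c("II", "II", "I")),
                                   "majority_2of3")$band_type, "II")
  expect_true(is.na(replicate_consensus(mk_mat(c("II", "II", "I")),
                                        "strict_identical")$band_type))
  expect_true(is.na(replicate_consensus(mk_mat(c("I", "II", "III")),
                                        "majority_2of3")$band_type))
  expect_equal(replicate_consensus(mk_mat(c("III", "III", "III")),
                                   "strict_identical")$band_type, "III")
})

test_that("strict consensus retains a subset of majority-consensus loci", {
  co <- small_cohort(seed = 51, kb = 20)
  pk <- emit_peak_tables(co, replicates = 3,
                         noise = msap_noise(dropout_prob = 0.15,
                                            height_sdlog = 0.3), seed = 52)
  sc <- score_peak_table(pk)
  maj <- replicate_consensus(sc$matrix, "majority_2of3")
  str <- replicate_consensus(sc$matrix, "strict_identical")
  kept_maj <- paste(maj$locus, maj$genotype)[!is.na(maj$band_type)]
  kept_str <- paste(str$locus, str$genotype)[!is.na(str$band_type)]
  expect_true(all(kept_str %in% kept_maj))
  # and where both keep a locus they agree
  common <- intersect(kept_str, kept_maj)
  expect_equal(str$band_type[match(common, paste(str$locus, str$genotype))],
               maj$band_type[match(common, paste(maj$locus, maj$genotype))])
})

test_that("noise-free scoring reproduces the simulator's planted truth exactly", {
  co <- small_cohort(seed = 61, kb = 30)
  tr <- truth_band_types(co)
  pk <- emit_peak_tables(co, replicates = 3, seed = 62)
  sc <- score_peak_table(pk)
  w <- band_matrix(sc$matrix)
  expect_setequal(w$locus, tr$locus)
  m <- merge(tr, w, by = "locus")
  for (g in c("WT", "NEG", "POS")) for (r in 1:3)
    expect_equal(m[[sprintf("%s_R%d", g, r)]], m[[g]],
                 label = sprintf("%s_R%d", g, r))
})
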