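# Independent oracles and hand-built fixtures, kept deliberately naive:
# plain loops and substr(), no reuse of the package's vectorised paths.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# naive motif scan: 0-based starts
oracle_scan <- function(seq, motif) {
  k <- nchar(motif)
  hits <- integer(0)
  for (i in seq_len(nchar(seq) - k + 1)) {
    if (substr(seq, i, i + k - 1) == motif) hits <- c(hits, i - 1L)
  }
  hits
}

# brute-force amplicon enumeration for one lane of a single-chromosome
# genome: try every ordered cut pair, demand no intervening cut, one EcoRI
# and one HM end, matching selective suffixes, size strictly inside window
oracle_amplicons <- function(seq, methylome, enzyme_hm, e_suffix = "",
                             hm_suffix = "", window = c(50, 500), offset = 0) {
  e_cuts <- oracle_scan(seq, "GAATTC") + 1L
  ccgg <- oracle_scan(seq, "CCGG")
  hm_cuts <- integer(0)
  for (s in ccgg) {
    st <- methylome$status[methylome$pos == s]
    cut <- if (enzyme_hm == "MspI") TRUE else identical(st, "unmethylated")
    if (cut) hm_cuts <- c(hm_cuts, s + 1L)
  }
  all_cuts <- sort(c(e_cuts, hm_cuts))
  out <- NULL
  for (c1 in all_cuts) for (c2 in all_cuts) {
    if (c2 <= c1) next
    if (any(all_cuts > c1 & all_cuts < c2)) next
    left_e <- c1 %in% e_cuts
    right_e <- c2 %in% e_cuts
    if (left_e == right_e) next
    size <- (c2 - c1) + offset
    if (!(size > window[1] && size < window[2])) next
    ke <- nchar(e_suffix); kh <- nchar(hm_suffix)
    ok <- TRUE
    if (left_e) {
      if (ke > 0 && substr(seq, c1 + 6, c1 + 5 + ke) != e_suffix) ok <- FALSE
      if (kh > 0 &&
          oracle_revcomp(substr(seq, c2 - kh, c2 - 1)) != hm_suffix) ok <- FALSE
    } else {
      if (kh > 0 && substr(seq, c1 + 4, c1 + 3 + kh) != hm_suffix) ok <- FALSE
      if (ke > 0 &&
          oracle_revcomp(substr(seq, c2 - ke, c2 - 1)) != e_suffix) ok <- FALSE
    }
    if (ok) out <- rbind(out, data.frame(start = c1, end = c2, size = size))
  }
  if (is.null(out)) data.frame(start = integer(0), end = integer(0),
                               size = numeric(0))
  else out[order(out$start), , drop = FALSE]
}

# naive O(n^2) single-linkage clustering at cutoff tol (no width refinement)
oracle_single_linkage <- function(sizes, tol) {
  n <- length(sizes)
  lab <- seq_len(n)
  repeat {
    merged <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (lab[i] != lab[j] && abs(sizes[i] - sizes[j]) <= tol) {
        lab[lab == lab[j]] <- lab[i]
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  match(lab, unique(lab))
}

# hand-assembled genome with one nested CCGG pair between two EcoRI sites:
# E ... CCGG(internal) ... CCGG(external) ... E
nested_pair_genome <- function() {
  sp <- function(n) paste(rep("A", n), collapse = "")
  seq <- paste0(sp(10), "GAATTC", sp(80), "CCGG", sp(60), "CCGG", sp(100),
                "GAATTC", sp(10))
  e2 <- 10 + 6 + 80 + 4 + 60 + 4 + 100
  structure(list(
    seq = c(chr1 = seq),
    ecori = data.frame(chrom = "chr1", start = c(10L, as.integer(e2))),
    ccgg = data.frame(chrom = "chr1", start = c(96L, 160L), unit = 1L,
                      nested = TRUE, role = c("internal", "external")),
    params = list()), class = "msap_genome")
}

nested_methylome <- function(int_status, ext_status) {
  m <- data.frame(chrom = "chr1", pos = c(96L, 160L),
                  status = c(int_status, ext_status))
  class(m) <- c("msap_methylome", "data.frame")
  m
}

# small simulated cohort used across tests
small_cohort <- function(seed = 7, nested_fraction = 0.25,
                         config = genotype_effect_config(), kb = 40) {
  g <- generate_genome(1, kb * 1000, 2, 2, nested_fraction, seed = seed)
  m <- generate_methylome(g, 0.55, seed = seed + 1)
  apply_genotype_effects(g, m, config, seed = seed + 2)
}

# expand per-sample band-type counts into a coded msap_matrix
matrix_from_counts <- function(counts) {
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    types <- rep(c("I", "II", "III", "IV"),
                 c(counts$n_I[i], counts$n_II[i], counts$n_III[i],
                   counts$n_IV[i]))
    rows[[i]] <- data.frame(
      locus = sprintf("L%05d", seq_along(types)),
      sample = sprintf("%s_R%d", counts$genotype[i], counts$replicate[i]),
      genotype = counts$genotype[i], replicate = counts$replicate[i],
      band_type = types)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("msap_matrix", "data.frame")
  out
}
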