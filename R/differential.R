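#' Genotype comparison, DAL/DML tallies and the inheritance partition
#'
#' A locus is differentially amplified (DAL) when its consensus band type
#' differs between any two genotypes; a DAL is differentially methylated
#' (DML) when its transition maps to hyper- or hypomethylation under the
#' twelve-transition model. Changed loci partition by which offspring
#' genotype carries the change: only the transgene-negative offspring, only
#' the positive, or both (the same changed type in both — the candidate
#' intergenerationally inherited class). Loci changed in both offspring but
#' to different types fit none of those columns and are reported separately
#' as "inconsistent".
#'
#' @name differential-analysis
NULL

#' Per-sample band-type counts and methylation ratios
#'
#' @param matrix an `msap_matrix` from [code_samples()].
#' @return data.frame, one row per sample: `sample`, `genotype`,
#'   `replicate`, `n_I..n_IV`, `total`, `methylation_pct`,
#'   `unmethylation_pct`.
#' @export
tabulate_band_types <- function(matrix) {
  df <- as.data.frame(matrix)
  samples <- unique(df[, c("sample", "genotype", "replicate")])
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    x <- df$band_type[df$sample == samples$sample[i]]
    n <- vapply(BAND_LEVELS, function(b) sum(x == b), integer(1))
    cnt <- band_type_counts(n[["I"]], n[["II"]], n[["III"]], n[["IV"]])
    pct <- methylation_ratio(cnt)
    data.frame(samples[i, ], n_I = cnt$n_I, n_II = cnt$n_II,
               n_III = cnt$n_III, n_IV = cnt$n_IV, total = cnt$total,
               methylation_pct = pct,
               unmethylation_pct = round_half_up(100 - pct, 2))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

#' Compare offspring consensus types with the wild type
#'
#' Loci excluded (no consensus) in any genotype are dropped. A locus is a
#' DAL iff at least one of WT->NEG, WT->POS, NEG->POS is a non-identity
#' transition.
#'
#' @param consensus an `msap_consensus` covering genotypes `wt`, `neg`,
#'   `pos`.
#' @param wt,neg,pos genotype labels (defaults WT/NEG/POS).
#' @return data.frame of class `msap_comparison`: `locus`, `wt`, `neg`,
#'   `pos`, `changed`; the number of consensus-excluded loci is attached as
#'   attribute `"n_excluded"`.
#' @export
compare_to_wildtype <- function(consensus, wt = "WT", neg = "NEG", pos = "POS") {
  df <- as.data.frame(consensus)
  need <- c(wt, neg, pos)
  if (!all(need %in% df$genotype))
    stop("consensus must cover genotypes: ", paste(need, collapse = ", "),
         call. = FALSE)
  w <- df[df$genotype == wt, c("locus", "band_type")]
  names(w)[2] <- "wt"
  n <- df[df$genotype == neg, c("locus", "band_type")]
  names(n)[2] <- "neg"
  p <- df[df$genotype == pos, c("locus", "band_type")]
  names(p)[2] <- "pos"
  m <- merge(merge(w, n, by = "locus"), p, by = "locus")
  keep <- stats::complete.cases(m)
  n_excluded <- sum(!keep)
  m <- m[keep, ]
  m$changed <- m$wt != m$neg | m$wt != m$pos | m$neg != m$pos
  rownames(m) <- NULL
  attr(m, "n_excluded") <- n_excluded
  class(m) <- c("msap_comparison", "data.frame")
  m
}

#' Partition changed loci by offspring sharing
#'
#' @param comparison an `msap_comparison`.
#' @return list of class `inheritance_partition`:
#'   \describe{
#'     \item{loci}{per-DAL data.frame: `locus`, `wt`, `neg`, `pos`,
#'       `partition` (only_negative / only_positive / both / inconsistent),
#'       `from_type`, `to_type` (NA for inconsistent loci),
#'       `methylation_variation`, `sequence_change`}
#'     \item{summary}{12 transitions x 3 partition columns count table,
#'       Table-3 shaped, plus a `Total` row}
#'     \item{n_unchanged, n_dal, n_inconsistent}{tallies}
#'   }
#' @export
partition_inheritance <- function(comparison) {
  df <- as.data.frame(comparison)
  dal <- df[df$changed, , drop = FALSE]
  part <- with(dal, ifelse(
    neg == pos & neg != wt, "both",
    ifelse(neg != wt & pos == wt, "only_negative",
           ifelse(pos != wt & neg == wt, "only_positive", "inconsistent"))))
  dal$partition <- part
  dal$from_type <- dal$wt
  dal$to_type <- ifelse(part == "both", dal$neg,
                        ifelse(part == "only_negative", dal$neg,
                               ifelse(part == "only_positive", dal$pos,
                                      NA_character_)))
  cls <- classify_transition(
    ifelse(is.na(dal$to_type), dal$wt, dal$from_type),
    ifelse(is.na(dal$to_type), dal$wt, dal$to_type))
  dal$sequence_change <- ifelse(is.na(dal$to_type), NA_character_,
                                cls$sequence_change)
  dal$methylation_variation <- ifelse(is.na(dal$to_type), NA_character_,
                                      cls$methylation_variation)

  tm <- transition_model()
  cols <- c("only_negative", "only_positive", "both")
  summary <- tm[, c("from_type", "to_type")]
  for (cc in cols) {
    summary[[cc]] <- mapply(function(f, t)
      sum(dal$partition == cc & dal$from_type == f & dal$to_type == t,
          na.rm = TRUE),
      summary$from_type, summary$to_type)
  }
  total <- data.frame(from_type = "Total", to_type = "",
                      t(colSums(summary[cols])))
  names(total) <- names(summary)
  summary <- rbind(summary, total)
  rownames(summary) <- NULL

  structure(list(
    loci = dal[, c("locus", "wt", "neg", "pos", "partition", "from_type",
                   "to_type", "sequence_change", "methylation_variation")],
    summary = summary,
    n_unchanged = sum(!df$changed),
    n_dal = nrow(dal),
    n_inconsistent = sum(part == "inconsistent")
  ), class = "inheritance_partition")
}

#' DML tallies and fractions over a partition
#'
#' Applies the transition model's methylation verdict to every changed
#' locus and reports hyper/hypo counts per partition column, the DML/DAL
#' fraction, the hyper and hypo fractions of the offspring-shared ("both")
#' column, and the share of all DMLs that is intergenerationally
#' inheritable (the "both" column DMLs). Every reported percentage names
#' its denominator. Percentages are half-up rounded to 2 decimals.
#'
#' @param partition an `inheritance_partition`.
#' @param n_total optional total scored loci, to also report the
#'   unchanged-locus fraction.
#' @return list of class `dml_summary`: `counts` (per-partition hyper/hypo/
#'   unchanged-variation tallies), `dml_total`, `dal_total` and `fractions`
#'   (data.frame metric / numerator / denominator / percent).
#' @export
count_dml <- function(partition, n_total = NULL) {
  stopifnot(inherits(partition, "inheritance_partition"))
  loci <- partition$loci
  cols <- c("only_negative", "only_positive", "both")
  counts <- data.frame(partition = cols)
  for (v in c("hypermethylation", "hypomethylation", "unchanged")) {
    counts[[v]] <- vapply(cols, function(cc)
      sum(loci$partition == cc & loci$methylation_variation == v, na.rm = TRUE),
      integer(1))
  }
  dml_flag <- loci$methylation_variation %in% c("hypermethylation", "hypomethylation")
  dml_total <- sum(dml_flag)
  dal_total <- partition$n_dal
  n_both <- sum(loci$partition == "both")
  hyper_both <- counts$hypermethylation[counts$partition == "both"]
  hypo_both <- counts$hypomethylation[counts$partition == "both"]
  inheritable <- hyper_both + hypo_both

  frac <- function(metric, num, den) data.frame(
    metric = metric, numerator = num, denominator = den,
    percent = if (den > 0) round_half_up(100 * num / den, 2) else NA_real_)
  fractions <- rbind(
    frac("DML / DAL", dml_total, dal_total),
    frac("hypermethylated shared DML / shared DAL", hyper_both, n_both),
    frac("hypomethylated shared DML / shared DAL", hypo_both, n_both),
    frac("inheritable DML / all DML", inheritable, dml_total)
  )
  if (!is.null(n_total)) {
    fractions <- rbind(
      fractions,
      frac("unchanged loci / all loci", n_total - dal_total, n_total),
      frac("DAL / all loci", dal_total, n_total))
  }
  structure(list(counts = counts, dml_total = dml_total,
                 dal_total = dal_total, fractions = fractions),
            class = "dml_summary")
}

#' Expand a transition-count table into pseudo-loci
#'
#' Turns a Table-3-shaped count matrix (12 transitions x only-negative /
#' only-positive / both columns) into per-locus consensus calls, so the
#' count matrix can be fed through [compare_to_wildtype()],
#' [partition_inheritance()] and [count_dml()] like any scored cohort.
#' Optionally pads the universe with unchanged type-I loci up to
#' `n_total`.
#'
#' @param counts data.frame with columns `from_type`, `to_type`,
#'   `only_negative`, `only_positive`, `both`.
#' @param n_total optional total locus count; the remainder becomes
#'   unchanged loci.
#' @return an `msap_consensus` covering genotypes WT/NEG/POS.
#' @export
expand_transition_counts <- function(counts, n_total = NULL) {
  rows <- list()
  k <- 0
  add <- function(wt, neg, pos, n) {
    if (n == 0) return()
    ids <- sprintf("locus%06d", k + seq_len(n))
    k <<- k + n
    rows[[length(rows) + 1]] <<- data.frame(
      locus = rep(ids, 3),
      genotype = rep(c("WT", "NEG", "POS"), each = n),
      band_type = rep(c(wt, neg, pos), each = n))
  }
  for (i in seq_len(nrow(counts))) {
    f <- as.character(counts$from_type[i])
    t <- as.character(counts$to_type[i])
    add(f, t, f, counts$only_negative[i])
    add(f, f, t, counts$only_positive[i])
    add(f, t, t, counts$both[i])
  }
  if (!is.null(n_total)) {
    n_pad <- n_total - k
    if (n_pad < 0) stop("n_total smaller than the expanded loci", call. = FALSE)
    add("I", "I", "I", n_pad)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("msap_consensus", "data.frame")
  out
}

#' Pairwise t-tests on per-sample methylation ratios
#'
#' Welch's two-sample t-test (Student's by `var_equal = TRUE`) for every
#' genotype pair, flagged at alpha.
#'
#' @param ratios data.frame with columns `genotype` and `methylation_pct`
#'   (one row per sample), e.g. from [tabulate_band_types()].
#' @param var_equal use the pooled-variance Student test.
#' @param alpha significance level (default 0.05).
#' @return data.frame: `group1`, `group2`, `mean1`, `mean2`, `t`, `df`,
#'   `p_value`, `significant`.
#' @export
compare_ratio_means <- function(ratios, var_equal = FALSE, alpha = 0.05) {
  gs <- unique(ratios$genotype)
  pairs <- utils::combn(gs, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    x <- ratios$methylation_pct[ratios$genotype == pr[1]]
    y <- ratios$methylation_pct[ratios$genotype == pr[2]]
    if (length(x) < 2 || length(y) < 2)
      stop("at least 2 replicates per genotype are required", call. = FALSE)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      # degenerate noise-free case: identical replicates have no within-group
      # variance, so the statistic is 0 (equal means) or infinite
      eq <- mean(x) == mean(y)
      stat <- if (eq) 0 else sign(mean(x) - mean(y)) * Inf
      pv <- if (eq) 1 else 0
      tt <- list(statistic = stat, parameter = NA_real_, p.value = pv)
    } else {
      tt <- stats::t.test(x, y, var.equal = var_equal)
    }
    data.frame(group1 = pr[1], group2 = pr[2],
               mean1 = mean(x), mean2 = mean(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, significant = tt$p.value < alpha)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
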