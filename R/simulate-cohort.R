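#' Simulated cohorts: genotype effects, truth tables, peak emission
#'
#' A cohort holds three genotype states derived from one base genome +
#' methylome: the wild type (WT, unchanged), and two offspring genotypes
#' (NEG, the transgene-negative offspring; POS, the transgene-positive
#' offspring) that receive planted hyper-/hypomethylation events and CCGG
#' gain/loss mutations. Each event is tagged as shared by both offspring
#' genotypes or private to one, which is the ground truth for the
#' inheritance partition.
#'
#' @name simulated-cohort
NULL

GENOTYPES <- c("WT", "NEG", "POS")

#' Genotype-effect configuration
#'
#' Rates are fractions of CCGG sites receiving each event type (at most one
#' event per site). `shared_fraction` is the probability an event is planted
#' in both offspring genotypes; private events split evenly between NEG and
#' POS. Defaults approximate the changed-locus load and the roughly 42%
#' offspring-shared fraction seen in the rat sperm cohort this package
#' models.
#'
#' @param hyper_rate fraction of sites gaining internal-CpG methylation.
#' @param hypo_rate fraction of sites losing it.
#' @param gain_rate fraction of inter-EcoRI intervals receiving a new CCGG.
#' @param loss_rate fraction of sites whose CCGG is mutated away.
#' @param shared_fraction probability an event is shared by NEG and POS.
#' @param gain_meth_prob probability a gained CCGG arrives methylated
#'   (a new CmCGG rather than a new CCGG).
#' @return list of class `genotype_effect_config`.
#' @export
genotype_effect_config <- function(hyper_rate = 0.06, hypo_rate = 0.045,
                                   gain_rate = 0.02, loss_rate = 0.02,
                                   shared_fraction = 0.42,
                                   gain_meth_prob = 0.5) {
  rates <- c(hyper_rate, hypo_rate, gain_rate, loss_rate,
             shared_fraction, gain_meth_prob)
  if (any(rates < 0) || any(rates > 1))
    stop("rates and fractions must lie in [0, 1]", call. = FALSE)
  structure(list(hyper_rate = hyper_rate, hypo_rate = hypo_rate,
                 gain_rate = gain_rate, loss_rate = loss_rate,
                 shared_fraction = shared_fraction,
                 gain_meth_prob = gain_meth_prob),
            class = "genotype_effect_config")
}

# Substitute a CCGG motif into the spacer between an EcoRI site and the
# first CCGG of its interval; returns new 0-based position or NA.
plant_ccgg <- function(seq, e_start, c_start) {
  gap_lo <- e_start + 6L + 5L
  gap_hi <- c_start - 5L - 4L
  if (gap_hi <= gap_lo) return(list(seq = seq, pos = NA_integer_))
  for (try in 1:10) {
    p <- sample_int(gap_lo, gap_hi)
    cand <- seq
    substr(cand, p + 1L, p + 4L) <- CCGG_MOTIF
    w_from <- max(0L, p - 6L)
    w_to <- min(nchar(cand), p + 10L)
    win <- substr0(cand, w_from, w_to)
    n_ccgg <- length(motif_starts0(win, CCGG_MOTIF))
    n_eco <- length(motif_starts0(win, ECORI_MOTIF))
    if (n_ccgg == 1 && n_eco == 0)
      return(list(seq = cand, pos = p))
  }
  list(seq = seq, pos = NA_integer_)
}

# Mutate a CCGG away (CCGG -> CTGG, re-checked for accidental motifs).
ablate_ccgg <- function(seq, c_start) {
  for (base in c("T", "A")) {
    cand <- seq
    substr(cand, c_start + 2L, c_start + 2L) <- base
    win <- substr0(cand, max(0L, c_start - 6L), min(nchar(cand), c_start + 10L))
    if (length(motif_starts0(win, CCGG_MOTIF)) == 0 &&
        length(motif_starts0(win, ECORI_MOTIF)) == 0)
      return(cand)
  }
  seq
}

#' Plant genotype effects on a base genome + methylome
#'
#' The wild type keeps the base state. Each planted event (hypermethylation,
#' hypomethylation, CCGG gain, CCGG loss) is assigned a scope — shared by
#' both offspring genotypes, or private to NEG or POS — and applied to the
#' corresponding genotype states. The returned event table is the planted
#' ground truth for recovery tests.
#'
#' @param genome base `msap_genome`.
#' @param methylome base `msap_methylome`.
#' @param config a [genotype_effect_config()].
#' @param seed integer seed.
#' @return object of class `msap_cohort`: list with `genotypes` (named list
#'   WT/NEG/POS of `list(genome, methylome)`), `events` (data.frame:
#'   `event_id`, `type`, `chrom`, `pos`, `scope`) and `config`.
#' @export
apply_genotype_effects <- function(genome, methylome, config = genotype_effect_config(),
                                   seed = 1) {
  stopifnot(inherits(genome, "msap_genome"),
            inherits(config, "genotype_effect_config"))
  set.seed(seed)
  n_sites <- nrow(genome$ccgg)
  key <- paste(methylome$chrom, methylome$pos)
  gkey <- paste(genome$ccgg$chrom, genome$ccgg$start)
  st <- methylome$status[match(gkey, key)]

  avail <- seq_len(n_sites)
  pick <- function(eligible, n) {
    pool <- intersect(avail, eligible)
    n <- min(n, length(pool))
    sel <- if (n > 0) sample_vec(pool, n) else integer(0)
    avail <<- setdiff(avail, sel)
    sel
  }
  i_hyper <- pick(which(st == "unmethylated"), round(config$hyper_rate * n_sites))
  i_hypo <- pick(which(st == "internal_methylated"), round(config$hypo_rate * n_sites))
  i_loss <- pick(seq_len(n_sites), round(config$loss_rate * n_sites))

  picked <- c(i_hyper, i_hypo, i_loss)
  events <- data.frame(
    type = rep(c("hyper", "hypo", "loss"),
               c(length(i_hyper), length(i_hypo), length(i_loss))),
    chrom = genome$ccgg$chrom[picked],
    pos = genome$ccgg$start[picked],
    gain_meth = rep(NA, length(picked))
  )

  # gains: pick inter-EcoRI intervals whose sites are untouched by other
  # events, and fix the new CCGG position once on the base sequence so a
  # shared gain lands identically in both carrier genotypes
  n_gain <- round(config$gain_rate * nrow(genome$ecori))
  gain_rows <- list()
  if (n_gain > 0) {
    unit_of <- split(seq_len(n_sites), paste(genome$ccgg$chrom, genome$ccgg$unit))
    untouched <- vapply(unit_of, function(ix) all(ix %in% avail), logical(1))
    cand_units <- names(unit_of)[untouched]
    cand_units <- sample_vec(cand_units, min(n_gain, length(cand_units)))
    for (u in cand_units) {
      ix <- unit_of[[u]]
      first <- ix[which.min(genome$ccgg$start[ix])]
      ch <- genome$ccgg$chrom[first]
      e_of_unit <- genome$ecori$start[genome$ecori$chrom == ch]
      e_prev <- max(e_of_unit[e_of_unit < genome$ccgg$start[first]])
      res <- plant_ccgg(genome$seq[[ch]], e_prev, genome$ccgg$start[first])
      if (is.na(res$pos)) next
      gain_rows[[length(gain_rows) + 1]] <- data.frame(
        type = "gain", chrom = ch, pos = res$pos,
        gain_meth = runif(1) < config$gain_meth_prob,
        unit = genome$ccgg$unit[first]
      )
    }
  }

  events$unit <- rep(NA_integer_, nrow(events))
  if (length(gain_rows)) events <- rbind(events, do.call(rbind, gain_rows))
  if (nrow(events)) {
    scope_draw <- runif(nrow(events))
    events$scope <- ifelse(scope_draw < config$shared_fraction, "both",
                           ifelse(runif(nrow(events)) < 0.5, "neg_only", "pos_only"))
  } else {
    events$scope <- character(0)
  }
  events$event_id <- seq_len(max(nrow(events), 0))

  carriers <- list(NEG = c("both", "neg_only"), POS = c("both", "pos_only"))
  genotypes <- list(WT = list(genome = genome, methylome = methylome))
  for (g in names(carriers)) {
    gg <- genome
    mm <- methylome
    ev <- events[events$scope %in% carriers[[g]], , drop = FALSE]
    for (r in seq_len(nrow(ev))) {
      e <- ev[r, ]
      if (e$type %in% c("hyper", "hypo")) {
        j <- which(mm$chrom == e$chrom & mm$pos == e$pos)
        mm$status[j] <- if (e$type == "hyper") "internal_methylated" else "unmethylated"
      } else if (e$type == "loss") {
        gg$seq[[e$chrom]] <- ablate_ccgg(gg$seq[[e$chrom]], e$pos)
        drop <- gg$ccgg$chrom == e$chrom & gg$ccgg$start == e$pos
        gg$ccgg <- gg$ccgg[!drop, ]
        mm <- mm[!(mm$chrom == e$chrom & mm$pos == e$pos), ]
      } else if (e$type == "gain") {
        substr(gg$seq[[e$chrom]], e$pos + 1L, e$pos + 4L) <- CCGG_MOTIF
        gg$ccgg <- rbind(gg$ccgg, data.frame(
          chrom = e$chrom, start = e$pos, unit = e$unit,
          nested = TRUE, role = "internal"))
        mm <- rbind(as.data.frame(mm), data.frame(
          chrom = e$chrom, pos = e$pos,
          status = if (isTRUE(e$gain_meth)) "internal_methylated" else "unmethylated"))
        class(mm) <- c("msap_methylome", "data.frame")
      }
    }
    genotypes[[g]] <- list(genome = gg, methylome = mm)
  }
  events <- events[, c("event_id", "type", "chrom", "pos", "gain_meth", "scope")]
  structure(list(genotypes = genotypes, events = events, config = config,
                 seed = seed),
            class = "msap_cohort")
}

# sample() that never misreads a scalar as a range
sample_vec <- function(x, n) x[sample.int(length(x), n)]

#' Planted per-locus band-type truth of a cohort
#'
#' Runs the noise-free digestion/amplification model for every genotype and
#' codes each locus (primer pair x detected size) from lane presence. The
#' locus universe is every (primer pair, size) observed in any genotype and
#' lane; loci absent from both lanes of a genotype code IV there.
#'
#' @param cohort an `msap_cohort`.
#' @param primers primer panel.
#' @param size_window,size_offset as in [enumerate_amplicons()].
#' @return data.frame: `locus`, `primer_pair`, `size_bp`, `chrom`, `start`,
#'   `end`, and one band-type column per genotype (`WT`, `NEG`, `POS`).
#' @export
truth_band_types <- function(cohort, primers = primer_panel(0, 0),
                             size_window = c(50, 500), size_offset = 0) {
  stopifnot(inherits(cohort, "msap_cohort"))
  frs <- lapply(names(cohort$genotypes), function(g) {
    s <- cohort$genotypes[[g]]
    fr <- msap_fragments(s$genome, s$methylome, primers, size_window, size_offset)
    if (nrow(fr)) fr$genotype <- g else fr$genotype <- character(0)
    fr
  })
  frs <- do.call(rbind, frs)
  if (nrow(frs) == 0)
    return(data.frame(locus = character(0)))
  # same id scheme as bin_loci() so noise-free scoring aligns exactly
  frs$locus <- sprintf("%s@%.1f", frs$primer_pair, frs$size_bp)
  loci <- frs[!duplicated(frs$locus),
              c("locus", "primer_pair", "size_bp", "chrom", "start", "end")]
  for (g in names(cohort$genotypes)) {
    msp <- loci$locus %in% frs$locus[frs$genotype == g & frs$lane == MSP_LANE]
    hpa <- loci$locus %in% frs$locus[frs$genotype == g & frs$lane == HPA_LANE]
    loci[[g]] <- as.character(code_band_type(msp, hpa))
  }
  rownames(loci) <- NULL
  loci
}

#' Noise model for peak emission
#'
#' @param dropout_prob per-peak probability a true fragment is missed.
#' @param spurious_rate expected spurious peaks per sample x lane (Poisson).
#' @param size_jitter_sd s.d. of Gaussian sizing error (bp).
#' @param height_meanlog,height_sdlog log-normal peak-height parameters
#'   (RFU); the default median of 5000 sits above the 1000-RFU filter, and
#'   `height_sdlog = 0` makes heights deterministic.
#' @return list of class `msap_noise`.
#' @export
msap_noise <- function(dropout_prob = 0, spurious_rate = 0,
                       size_jitter_sd = 0, height_meanlog = log(5000),
                       height_sdlog = 0) {
  stopifnot(dropout_prob >= 0, dropout_prob <= 1, spurious_rate >= 0,
            size_jitter_sd >= 0, height_sdlog >= 0)
  structure(list(dropout_prob = dropout_prob, spurious_rate = spurious_rate,
                 size_jitter_sd = size_jitter_sd,
                 height_meanlog = height_meanlog,
                 height_sdlog = height_sdlog),
            class = "msap_noise")
}

#' Emit replicate peak tables from a cohort
#'
#' Produces the capillary-electrophoresis-style peak table for every
#' genotype x replicate x lane. The default noise model is exact: no
#' dropout, no spurious peaks, no sizing jitter, constant height — so the
#' scored matrix reproduces [truth_band_types()] exactly. Deterministic
#' under a fixed seed.
#'
#' @param cohort an `msap_cohort`.
#' @param primers primer panel.
#' @param replicates biological replicates per genotype (default 3).
#' @param noise an [msap_noise()].
#' @param seed integer seed.
#' @param size_window,size_offset as in [enumerate_amplicons()].
#' @return data.frame with columns `sample`, `genotype`, `replicate`,
#'   `lane`, `primer_pair`, `size_bp`, `height`.
#' @export
emit_peak_tables <- function(cohort, primers = primer_panel(0, 0),
                             replicates = 3, noise = msap_noise(), seed = 1,
                             size_window = c(50, 500), size_offset = 0) {
  stopifnot(inherits(cohort, "msap_cohort"), replicates >= 1)
  set.seed(seed)
  out <- list()
  for (g in names(cohort$genotypes)) {
    s <- cohort$genotypes[[g]]
    fr <- msap_fragments(s$genome, s$methylome, primers, size_window, size_offset)
    for (r in seq_len(replicates)) {
      for (ln in msap_lanes()) {
        f <- fr[fr$lane == ln, , drop = FALSE]
        keep <- runif(nrow(f)) >= noise$dropout_prob
        f <- f[keep, , drop = FALSE]
        n <- nrow(f)
        size <- f$size_bp + if (noise$size_jitter_sd > 0)
          stats::rnorm(n, 0, noise$size_jitter_sd) else 0
        height <- stats::rlnorm(n, noise$height_meanlog, noise$height_sdlog)
        tab <- data.frame(
          sample = sprintf("%s_R%d", g, r), genotype = g, replicate = r,
          lane = ln, primer_pair = f$primer_pair, size_bp = size,
          height = height)
        n_spur <- if (noise$spurious_rate > 0) stats::rpois(1, noise$spurious_rate) else 0
        if (n_spur > 0) {
          tab <- rbind(tab, data.frame(
            sample = sprintf("%s_R%d", g, r), genotype = g, replicate = r,
            lane = ln,
            primer_pair = sample_vec(primers$primer_pair, n_spur),
            size_bp = stats::runif(n_spur, size_window[1] + 1, size_window[2] - 1),
            height = stats::rlnorm(n_spur, noise$height_meanlog,
                                   max(noise$height_sdlog, 0.3))))
        }
        out[[length(out) + 1]] <- tab
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a peak table as CSV
#' @param peaks peak table from [emit_peak_tables()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.csv(peaks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a peak table CSV
#' @param path CSV with header sample, genotype, replicate, lane,
#'   primer_pair, size_bp, height.
#' @return peak table data.frame.
#' @export
read_peak_table <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "genotype", "replicate", "lane", "primer_pair",
            "size_bp", "height")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("peak table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  p
}

#' Write the planted event truth as TSV
#' @param cohort an `msap_cohort`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(cohort, path) {
  utils::write.table(cohort$events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
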