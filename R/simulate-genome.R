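#' Synthetic genomes for in-silico MSAP
#'
#' The generator builds each chromosome from repeating units
#' `GAATTC | spacer | CCGG [| spacer | CCGG] | spacer` so that every EcoRI
#' and CCGG site is planted at a known coordinate and every inter-EcoRI
#' interval carries one CCGG, or two ("nested pair", the configuration
#' behind band type III). Spacers are motif-free, and the assembled sequence
#' is re-scanned so that accidental GAATTC/CCGG occurrences created at
#' junctions are scrubbed: the planted coordinate tables are exact.
#'
#' Coordinates are 0-based half-open throughout. CCGG is its own reverse
#' complement and GAATTC is palindromic, so a single-strand scan covers both
#' strands.
#'
#' @name synthetic-genome
NULL

ECORI_MOTIF <- "GAATTC"
CCGG_MOTIF <- "CCGG"
DNA_BASES <- c("A", "C", "G", "T")

random_bases <- function(n) {
  paste0(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# uniform integer draw on [lo, hi]; safe when lo == hi (sample() would
# misread a scalar as a range)
sample_int <- function(lo, hi) {
  if (hi <= lo) return(lo)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

motif_starts0 <- function(seq, motif) {
  # All 0-based start positions of motif. Neither GAATTC nor CCGG can
  # overlap a copy of itself (no proper prefix equals a suffix), so the
  # non-overlapping gregexpr scan is exhaustive.
  m <- gregexpr(motif, seq, fixed = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m) - 1L
}

# Replace accidental motif occurrences (0-based starts not in the planted
# sets) by mutating one base outside every planted motif footprint.
scrub_motifs <- function(seq, keep_ecori0, keep_ccgg0) {
  protected <- unique(c(
    unlist(lapply(keep_ecori0, function(s) s:(s + 5L))),
    unlist(lapply(keep_ccgg0, function(s) s:(s + 3L)))
  ))
  for (iter in 1:50) {
    bad <- c(
      setdiff(motif_starts0(seq, ECORI_MOTIF), keep_ecori0),
      setdiff(motif_starts0(seq, CCGG_MOTIF), keep_ccgg0)
    )
    if (length(bad) == 0) return(seq)
    for (s in bad) {
      span <- if (substr(seq, s + 1L, s + 6L) == ECORI_MOTIF) s:(s + 5L) else s:(s + 3L)
      editable <- setdiff(span, protected)
      if (length(editable) == 0) next  # fully inside planted sites; impossible
      p <- editable[1] + 1L  # to 1-based
      old <- substr(seq, p, p)
      substr(seq, p, p) <- sample(setdiff(DNA_BASES, old), 1)
    }
  }
  stop("failed to scrub accidental restriction motifs", call. = FALSE)
}

#' Generate a synthetic genome with planted EcoRI and CCGG sites
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome in bp (>= 1000).
#' @param ccgg_per_kb requested minimum CCGG density (sites/kb).
#' @param ecori_per_kb requested minimum EcoRI (GAATTC) density (sites/kb).
#' @param nested_fraction fraction of inter-EcoRI intervals carrying two
#'   CCGG sites (a nested pair) rather than one.
#' @param seed integer seed; the same seed reproduces the genome exactly.
#' @return object of class `msap_genome`: list with `seq` (named character
#'   vector of chromosome sequences), `ecori` and `ccgg` site tables
#'   (0-based motif start coordinates; `ccgg` additionally carries the unit
#'   index and `nested`/`role` columns), and `params`.
#' @export
generate_genome <- function(n_chrom = 1, chrom_length = 100000,
                            ccgg_per_kb = 2, ecori_per_kb = 2,
                            nested_fraction = 0.2, seed = 1) {
  if (chrom_length < 1000)
    stop("chrom_length must be at least 1 kb", call. = FALSE)
  set.seed(seed)
  n_units <- max(ceiling(ecori_per_kb * chrom_length / 1000),
                 ceiling(ccgg_per_kb * chrom_length / 1000))
  budget <- floor(chrom_length / n_units)
  # minimal unit: GAATTC + 40 + CCGG + (30 + CCGG) + 20
  if (budget < 6 + 4 + 4 + 40 + 30 + 20)
    stop("site density unattainable at this chromosome length", call. = FALSE)

  seqs <- character(n_chrom)
  ecori <- vector("list", n_chrom)
  ccgg <- vector("list", n_chrom)
  for (ci in seq_len(n_chrom)) {
    chrom <- sprintf("chr%d", ci)
    nested <- runif(n_units) < nested_fraction
    parts <- character(0)
    pos <- 0L
    e0 <- integer(0)
    c0 <- integer(0)
    cunit <- integer(0)
    cnested <- logical(0)
    crole <- character(0)
    for (u in seq_len(n_units)) {
      fixed <- 6L + 4L + if (nested[u]) 4L else 0L
      tail_min <- 20L
      avail <- budget - fixed - tail_min
      s_a <- sample_int(40L, min(250L, avail - if (nested[u]) 30L else 0L))
      s_b <- if (nested[u]) sample_int(30L, min(80L, avail - s_a)) else 0L
      s_c <- budget - fixed - s_a - s_b
      unit <- c(ECORI_MOTIF, random_bases(s_a), CCGG_MOTIF)
      e0 <- c(e0, pos)
      c0 <- c(c0, pos + 6L + s_a)
      cunit <- c(cunit, u)
      cnested <- c(cnested, nested[u])
      crole <- c(crole, if (nested[u]) "internal" else "single")
      if (nested[u]) {
        unit <- c(unit, random_bases(s_b), CCGG_MOTIF)
        c0 <- c(c0, pos + 6L + s_a + 4L + s_b)
        cunit <- c(cunit, u)
        cnested <- c(cnested, TRUE)
        crole <- c(crole, "external")
      }
      unit <- c(unit, random_bases(s_c))
      parts <- c(parts, unit)
      pos <- pos + budget
    }
    if (pos < chrom_length) parts <- c(parts, random_bases(chrom_length - pos))
    seq <- paste0(parts, collapse = "")
    seq <- scrub_motifs(seq, e0, c0)
    seqs[ci] <- seq
    names(seqs)[ci] <- chrom
    ecori[[ci]] <- data.frame(chrom = chrom, start = e0)
    ccgg[[ci]] <- data.frame(chrom = chrom, start = c0, unit = cunit,
                             nested = cnested, role = crole)
  }
  structure(
    list(
      seq = seqs,
      ecori = do.call(rbind, ecori),
      ccgg = do.call(rbind, ccgg),
      params = list(n_chrom = n_chrom, chrom_length = chrom_length,
                    ccgg_per_kb = ccgg_per_kb, ecori_per_kb = ecori_per_kb,
                    nested_fraction = nested_fraction, seed = seed)
    ),
    class = "msap_genome"
  )
}

#' @export
print.msap_genome <- function(x, ...) {
  cat(sprintf(
    "msap_genome: %d chromosome(s), %s bp total, %d EcoRI sites, %d CCGG sites (%d in nested pairs)\n",
    length(x$seq), format(sum(nchar(x$seq)), big.mark = ","),
    nrow(x$ecori), nrow(x$ccgg), sum(x$ccgg$nested)
  ))
  invisible(x)
}

#' Generate a methylome over a genome's CCGG sites
#'
#' Assigns each CCGG site an internal-CpG methylation status, symmetric on
#' both strands (mammalian CpG model; external-C and hemimethylation are not
#' modelled). The default methylated fraction mirrors the >50% sperm
#' methylation ratios the assay reports.
#'
#' @param genome an `msap_genome`.
#' @param meth_fraction probability a site starts methylated.
#' @param seed integer seed.
#' @return data.frame of class `msap_methylome` with columns `chrom`, `pos`
#'   (0-based CCGG start) and `status` in
#'   `c("unmethylated", "internal_methylated")`.
#' @export
generate_methylome <- function(genome, meth_fraction = 0.55, seed = 1) {
  stopifnot(inherits(genome, "msap_genome"))
  set.seed(seed)
  status <- ifelse(runif(nrow(genome$ccgg)) < meth_fraction,
                   "internal_methylated", "unmethylated")
  out <- data.frame(chrom = genome$ccgg$chrom, pos = genome$ccgg$start,
                    status = status)
  class(out) <- c("msap_methylome", "data.frame")
  out
}

#' Write genome chromosomes as FASTA
#' @param genome an `msap_genome`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "msap_genome"))
  x <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a genome from FASTA, rebuilding site tables by motif scan
#' @param path FASTA path.
#' @return an `msap_genome` (without unit/nesting annotation: `role` is
#'   reconstructed from inter-EcoRI interval occupancy).
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  eco <- do.call(rbind, lapply(names(seqs), function(ch)
    data.frame(chrom = ch, start = motif_starts0(seqs[[ch]], ECORI_MOTIF))))
  cc <- do.call(rbind, lapply(names(seqs), function(ch) {
    s <- motif_starts0(seqs[[ch]], CCGG_MOTIF)
    e <- motif_starts0(seqs[[ch]], ECORI_MOTIF)
    iv <- findInterval(s, sort(e))
    n_in_iv <- ave(s, iv, FUN = length)
    rank_in_iv <- ave(s, iv, FUN = seq_along)
    data.frame(chrom = ch, start = s, unit = iv, nested = n_in_iv > 1,
               role = ifelse(n_in_iv == 1, "single",
                             ifelse(rank_in_iv == 1, "internal", "external")))
  }))
  structure(list(seq = seqs, ecori = eco, ccgg = cc,
                 params = list(source = path)),
            class = "msap_genome")
}

#' Write a methylome truth table as TSV
#' @param methylome an `msap_methylome`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_methylome_tsv <- function(methylome, path) {
  utils::write.table(as.data.frame(methylome), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
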