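#' In-silico bisulfite sequencing PCR (BSP) cross-validation
#'
#' Bisulfite treatment converts unmethylated cytosine to uracil (read as
#' thymine after PCR) while methylated cytosine is unchanged. Sequencing
#' cloned PCR products therefore reads per-CpG methylation directly, which
#' cross-validates the MSAP band-type calls at the CCGG-internal CpG. Only
#' the sense strand is simulated: strand bookkeeping collapses after PCR
#' and T-vector cloning.
#'
#' @name bsp-validation
NULL

#' Bisulfite-convert a region sequence
#'
#' Every cytosine converts to T except those listed as methylated; with
#' conversion failure rate `f`, each unmethylated C is independently
#' retained as C with probability `f` (incomplete conversion).
#'
#' @param region sequence string (sense strand).
#' @param methylated_pos 1-based positions (within `region`) of methylated
#'   cytosines; positions not holding a C are an error.
#' @param conversion_failure_rate probability an unmethylated C escapes
#'   conversion.
#' @param seed integer seed (only consulted when the failure rate is
#'   positive).
#' @return converted sequence string.
#' @export
bisulfite_convert <- function(region, methylated_pos = integer(0),
                              conversion_failure_rate = 0, seed = NULL) {
  chars <- strsplit(region, "")[[1]]
  if (length(methylated_pos) && any(chars[methylated_pos] != "C"))
    stop("methylated_pos must index cytosines", call. = FALSE)
  is_c <- chars == "C"
  convert <- is_c
  convert[methylated_pos] <- FALSE
  if (conversion_failure_rate > 0) {
    if (!is.null(seed)) set.seed(seed)
    fail <- stats::runif(length(chars)) < conversion_failure_rate
    convert <- convert & !fail
  }
  chars[convert] <- "T"
  paste(chars, collapse = "")
}

#' Reference CpG positions of a region
#' @param region sequence string.
#' @return 1-based positions of the C of every CpG dinucleotide.
#' @export
cpg_positions <- function(region) {
  m <- gregexpr("CG", region, fixed = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m)
}

#' Call per-CpG methylation from sequenced clones
#'
#' At each reference CpG, a clone reading C is methylated and T
#' unmethylated; any other letter is uncallable and leaves the denominator.
#'
#' @param clones character vector of clone sequences (post-conversion,
#'   sense strand), each the full length of the reference region.
#' @param region the unconverted reference sequence.
#' @return data.frame: `position` (1-based C of each reference CpG),
#'   `n_meth`, `n_unmeth`, `n_uncallable`, `fraction` (n_meth over callable
#'   clones; NA when none are callable).
#' @export
call_clones <- function(clones, region) {
  if (any(nchar(clones) != nchar(region)))
    stop("clone length does not match the reference region", call. = FALSE)
  pos <- cpg_positions(region)
  rows <- lapply(pos, function(p) {
    obs <- substring(clones, p, p)
    n_meth <- sum(obs == "C")
    n_unmeth <- sum(obs == "T")
    n_unc <- length(obs) - n_meth - n_unmeth
    data.frame(position = p, n_meth = n_meth, n_unmeth = n_unmeth,
               n_uncallable = n_unc,
               fraction = if (n_meth + n_unmeth > 0)
                 n_meth / (n_meth + n_unmeth) else NA_real_)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Concordance between an MSAP call and a BSP methylation shift
#'
#' Concordant iff the sign of the clone-fraction difference between
#' genotypes matches the MSAP hyper/hypo direction and its magnitude
#' reaches the threshold.
#'
#' @param msap_call `"hypermethylation"` or `"hypomethylation"`.
#' @param bsp_delta offspring minus wild-type per-CpG methylated fraction.
#' @param threshold minimum |delta| (default 0.2, about 2 clones of 10).
#' @return `"concordant"` or `"discordant"`.
#' @export
concordance <- function(msap_call = c("hypermethylation", "hypomethylation"),
                        bsp_delta, threshold = 0.2) {
  msap_call <- match.arg(msap_call)
  want <- if (msap_call == "hypermethylation") 1 else -1
  ok <- sign(bsp_delta) == want & abs(bsp_delta) >= threshold
  ifelse(ok, "concordant", "discordant")
}

#' Simulate BSP clones for a genomic region
#'
#' Extracts the region from a genotype state, marks the internal CpG of
#' every methylated CCGG as methylated (all other cytosines, CpG or not,
#' convert — the simulator models methylation only at CCGG-internal CpGs),
#' and emits `n_clones` converted clone sequences.
#'
#' @param genome an `msap_genome`.
#' @param methylome the matching `msap_methylome`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open region bounds.
#' @param n_clones clones to emit (default 10).
#' @param conversion_failure_rate per-C failure probability.
#' @param seed integer seed.
#' @return list: `region` (reference sequence), `clones` (character
#'   vector), `ccgg_cpg_pos` (1-based positions, within the region, of
#'   CCGG-internal CpG cytosines), `calls` (from [call_clones()]).
#' @export
simulate_bsp_clones <- function(genome, methylome, chrom, start, end,
                                n_clones = 10, conversion_failure_rate = 0,
                                seed = 1) {
  stopifnot(inherits(genome, "msap_genome"))
  region <- substr0(genome$seq[[chrom]], start, end)
  mm <- methylome[methylome$chrom == chrom &
                    methylome$pos >= start & methylome$pos + 4 <= end, ]
  # CCGG at 0-based s: internal CpG cytosine at s+1 -> 1-based in-region
  meth_pos <- mm$pos[mm$status == "internal_methylated"] + 1L - start + 1L
  all_ccgg_cpg <- mm$pos + 1L - start + 1L
  set.seed(seed)
  clones <- vapply(seq_len(n_clones), function(i)
    bisulfite_convert(region, meth_pos, conversion_failure_rate, seed = NULL),
    character(1))
  list(region = region, clones = clones, ccgg_cpg_pos = all_ccgg_cpg,
       calls = call_clones(clones, region))
}

#' Write clones as FASTA
#' @param clones character vector of clone sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_clones_fasta <- function(clones, path) {
  x <- Biostrings::DNAStringSet(clones)
  names(x) <- sprintf("clone%02d", seq_along(clones))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read clones from FASTA
#' @param path FASTA path.
#' @return character vector of clone sequences.
#' @export
read_clones_fasta <- function(path) {
  as.character(Biostrings::readDNAStringSet(path))
}
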