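#' In-silico digestion and selective amplification
#'
#' `digest()` turns a genome + methylome into enzyme cut positions; MSAP
#' lane logic follows the isoschizomer rules: EcoRI cuts G^AATTC always,
#' MspI cuts C^CGG regardless of internal-CpG methylation, HpaII cuts only
#' unmethylated CCGG. `enumerate_amplicons()` reports the fragments a lane
#' amplifies: those spanning one EcoRI cut end and one MspI/HpaII cut end
#' with no internal cut in that lane, whose flanking bases match the
#' selective primer suffixes, and whose detected size (restriction length +
#' adapter/primer offset) falls strictly inside the size window.
#'
#' @name in-silico-digest
NULL

MSP_LANE <- "EcoRI+MspI"
HPA_LANE <- "EcoRI+HpaII"

#' MSAP lane labels
#' @return character vector of the two lane labels.
#' @export
msap_lanes <- function() c(MSP_LANE, HPA_LANE)

revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Digest a genome with one enzyme
#'
#' @param genome an `msap_genome`.
#' @param methylome an `msap_methylome` covering all CCGG sites of `genome`
#'   (ignored for EcoRI).
#' @param enzyme one of `"EcoRI"`, `"MspI"`, `"HpaII"`.
#' @return data.frame with columns `chrom`, `cut` (0-based cut position on
#'   the top strand: G^AATTC and C^CGG cut one base into the motif).
#' @export
digest <- function(genome, methylome, enzyme = c("EcoRI", "MspI", "HpaII")) {
  stopifnot(inherits(genome, "msap_genome"))
  enzyme <- match.arg(enzyme)
  if (enzyme == "EcoRI") {
    return(data.frame(chrom = genome$ecori$chrom,
                      cut = genome$ecori$start + 1L))
  }
  key_g <- paste(genome$ccgg$chrom, genome$ccgg$start)
  key_m <- paste(methylome$chrom, methylome$pos)
  i <- match(key_g, key_m)
  if (any(is.na(i)))
    stop("methylome does not cover all CCGG sites", call. = FALSE)
  st <- methylome$status[i]
  keep <- if (enzyme == "MspI") rep(TRUE, length(st)) else st == "unmethylated"
  data.frame(chrom = genome$ccgg$chrom[keep],
             cut = genome$ccgg$start[keep] + 1L)
}

#' A selective primer panel
#'
#' Builds primer pairs as combinations of EcoRI-side and HpaII/MspI-side
#' selective suffixes. The default panel of 4 x 16 = 64 pairs (one selective
#' base EcoRI-side, two HM-side) mirrors a 64-combination selective
#' amplification; suffix length 0 gives a single non-selective pair.
#'
#' @param e_len EcoRI-side suffix length (0-3).
#' @param hm_len HM-side suffix length (0-3).
#' @return data.frame with columns `primer_pair`, `e_suffix`, `hm_suffix`.
#' @export
primer_panel <- function(e_len = 1, hm_len = 2) {
  stopifnot(e_len %in% 0:3, hm_len %in% 0:3)
  mk <- function(k) {
    if (k == 0) return("")
    do.call(paste0, expand.grid(rep(list(DNA_BASES), k),
                                stringsAsFactors = FALSE)[, k:1, drop = FALSE])
  }
  es <- mk(e_len)
  hs <- mk(hm_len)
  g <- expand.grid(e_suffix = es, hm_suffix = hs, stringsAsFactors = FALSE)
  data.frame(
    primer_pair = sprintf("E%02d.HM%02d",
                          match(g$e_suffix, es), match(g$hm_suffix, hs)),
    e_suffix = g$e_suffix, hm_suffix = g$hm_suffix
  )
}

# 0-based substring helper: bases [from, to) of seq
substr0 <- function(seq, from, to) substring(seq, from + 1L, to)

#' Enumerate amplified fragments for one lane
#'
#' @param genome an `msap_genome`.
#' @param cuts_e EcoRI cut table from [digest()].
#' @param cuts_hm MspI or HpaII cut table from [digest()].
#' @param primers primer panel from [primer_panel()]; selective suffixes are
#'   matched against the genomic bases immediately inside each cut end
#'   (EcoRI side: beyond the GAATTC remnant; HM side: beyond the CCGG
#'   remnant, reverse-complemented when the primer reads the bottom strand).
#' @param size_window detected-size window (strict inequalities), default
#'   c(50, 500) bp.
#' @param size_offset constant adapter/primer contribution added to the
#'   restriction-fragment length to give the detected size (default 0).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open fragment interval between the two cuts), `e_side`
#'   (`"left"`/`"right"`), `primer_pair`, `size_bp`.
#' @export
enumerate_amplicons <- function(genome, cuts_e, cuts_hm, primers = primer_panel(0, 0),
                                size_window = c(50, 500), size_offset = 0) {
  stopifnot(inherits(genome, "msap_genome"))
  out <- vector("list", length(genome$seq))
  for (ci in seq_along(genome$seq)) {
    chrom <- names(genome$seq)[ci]
    seq <- genome$seq[[ci]]
    ce <- sort(cuts_e$cut[cuts_e$chrom == chrom])
    ch <- sort(cuts_hm$cut[cuts_hm$chrom == chrom])
    if (length(ce) == 0 || length(ch) == 0) next
    cuts <- rbind(data.frame(cut = ce, enz = "E"),
                  data.frame(cut = ch, enz = "HM"))
    cuts <- cuts[order(cuts$cut), ]
    n <- nrow(cuts)
    if (n < 2) next
    a <- cuts[-n, ]
    b <- cuts[-1, ]
    keep <- a$enz != b$enz
    if (!any(keep)) next
    fr <- data.frame(chrom = chrom, start = a$cut[keep], end = b$cut[keep],
                     e_side = ifelse(a$enz[keep] == "E", "left", "right"))
    # selective bases inward of each cut end (0-based coordinates):
    #  E on left : EcoRI motif starts at start-1, remnant AATTC ends at
    #              start+5 -> selective bases from start+5
    #  E on right: motif starts at end-1 -> bases before it, revcomp
    #  HM on left: CCGG starts at start-1, remnant CGG ends at start+3
    #  HM on right: CCGG starts at end-1 -> bases before it, revcomp
    # extract up to 3 selective bases inward of each end once, then match
    # every primer pair against those prefixes
    e_left <- fr$e_side == "left"
    K <- 3L
    e_sel <- ifelse(e_left,
                    substr0(seq, fr$start + 5L, fr$start + 5L + K),
                    revcomp(substr0(seq, fr$end - 1L - K, fr$end - 1L)))
    hm_sel <- ifelse(e_left,
                     revcomp(substr0(seq, fr$end - 1L - K, fr$end - 1L)),
                     substr0(seq, fr$start + 3L, fr$start + 3L + K))
    res <- vector("list", nrow(primers))
    for (pi in seq_len(nrow(primers))) {
      ok <- startsWith(e_sel, primers$e_suffix[pi]) &
        startsWith(hm_sel, primers$hm_suffix[pi])
      if (!any(ok)) next
      sub <- fr[ok, ]
      sub$primer_pair <- primers$primer_pair[pi]
      res[[pi]] <- sub
    }
    out[[ci]] <- do.call(rbind, res)
  }
  frs <- do.call(rbind, out)
  if (is.null(frs))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), e_side = character(0),
                      primer_pair = character(0), size_bp = numeric(0)))
  frs$size_bp <- (frs$end - frs$start) + size_offset
  frs <- frs[frs$size_bp > size_window[1] & frs$size_bp < size_window[2], ]
  rownames(frs) <- NULL
  frs
}

#' Amplified fragments for both MSAP lanes
#'
#' Runs [digest()] and [enumerate_amplicons()] for the EcoRI+MspI and
#' EcoRI+HpaII lanes of one sample state.
#'
#' @inheritParams enumerate_amplicons
#' @param methylome the sample's `msap_methylome`.
#' @return data.frame as [enumerate_amplicons()] with an extra `lane`
#'   column.
#' @export
msap_fragments <- function(genome, methylome, primers = primer_panel(0, 0),
                           size_window = c(50, 500), size_offset = 0) {
  cuts_e <- digest(genome, methylome, "EcoRI")
  lanes <- list(digest(genome, methylome, "MspI"),
                digest(genome, methylome, "HpaII"))
  names(lanes) <- msap_lanes()
  out <- lapply(names(lanes), function(ln) {
    fr <- enumerate_amplicons(genome, cuts_e, lanes[[ln]], primers,
                              size_window, size_offset)
    if (nrow(fr)) fr$lane <- ln else fr$lane <- character(0)
    fr
  })
  do.call(rbind, out)
}
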