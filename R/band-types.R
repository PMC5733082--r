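#' Band types and the transition classification model
#'
#' MSAP scores each locus in each sample from a pair of digestion lanes:
#' EcoRI+MspI ("M" lane) and EcoRI+HpaII ("H" lane). The two isoschizomers
#' recognise 5'-CCGG-3' but differ in methylation sensitivity: MspI cuts
#' C^CGG whether or not the internal CpG cytosine is methylated, while HpaII
#' is blocked by internal CpG methylation (CmCGG). Presence/absence over the
#' lane pair yields four band types:
#'
#' \describe{
#'   \item{I (1,1)}{unmethylated CCGG — cut, hence amplified, in both lanes}
#'   \item{II (1,0)}{fully methylated internal CpG (CmCGG) — M lane only}
#'   \item{III (0,1)}{H lane only; in vertebrates attributed to a nested
#'     CCGG pair whose internal site carries CmCGG (not plant-style
#'     hemimethylation)}
#'   \item{IV (0,0)}{absent from both lanes — site lost, or the nested-pair
#'     configurations that amplify in neither lane}
#' }
#'
#' Band types are stored as the (msp, hpa) bit pair; the Roman-numeral label
#' is presentation only.
#'
#' @name band-types
NULL

BAND_LEVELS <- c("I", "II", "III", "IV")

#' Code a band type from lane presence bits
#'
#' @param msp_present 0/1 (or logical) presence of the band in the
#'   EcoRI+MspI lane. Vectorised.
#' @param hpa_present 0/1 (or logical) presence in the EcoRI+HpaII lane.
#' @return factor with levels `c("I","II","III","IV")`.
#' @examples
#' code_band_type(1, 1)  # I
#' code_band_type(1, 0)  # II
#' code_band_type(c(0, 0), c(1, 0))  # III, IV
#' @export
code_band_type <- function(msp_present, hpa_present) {
  m <- as.integer(msp_present)
  h <- as.integer(hpa_present)
  if (any(is.na(m)) || any(is.na(h)) || any(!m %in% 0:1) || any(!h %in% 0:1))
    stop("presence indicators must be 0/1", call. = FALSE)
  if (length(m) != length(h))
    stop("msp_present and hpa_present must have equal length", call. = FALSE)
  # (1,1)->I (1,0)->II (0,1)->III (0,0)->IV
  idx <- c(`11` = 1L, `10` = 2L, `01` = 3L, `00` = 4L)[paste0(m, h)]
  factor(BAND_LEVELS[idx], levels = BAND_LEVELS)
}

#' Lane presence bits of a band type
#'
#' Inverse of [code_band_type()].
#'
#' @param type band type(s), as factor or character `"I".."IV"`.
#' @return data.frame with integer columns `msp_present`, `hpa_present`.
#' @export
band_type_bits <- function(type) {
  type <- as_band_type(type)
  data.frame(
    msp_present = as.integer(type %in% c("I", "II")),
    hpa_present = as.integer(type %in% c("I", "III"))
  )
}

as_band_type <- function(type) {
  if (is.factor(type)) type <- as.character(type)
  if (!all(type %in% BAND_LEVELS))
    stop("band type must be one of I, II, III, IV", call. = FALSE)
  factor(type, levels = BAND_LEVELS)
}

# The twelve-transition model: ordered band-type pairs -> sequence-change and
# methylation-variation verdicts. Hyper = gain of CmCGG (IV->II, I->II,
# I->III); hypo = loss of CmCGG (II->IV, II->I, III->I). IV<->III cannot be
# resolved (either direction is a move between nested-pair configurations)
# and is scored ambiguous / unchanged.
.transition_model <- local({
  m <- rbind(
    c("IV", "I",   "mutation",                 "unchanged"),
    c("IV", "II",  "mutation_and_epimutation", "hypermethylation"),
    c("IV", "III", "ambiguous",                "unchanged"),
    c("I",  "IV",  "mutation",                 "unchanged"),
    c("I",  "II",  "epimutation",              "hypermethylation"),
    c("I",  "III", "mutation_and_epimutation", "hypermethylation"),
    c("II", "IV",  "mutation_and_epimutation", "hypomethylation"),
    c("II", "I",   "epimutation",              "hypomethylation"),
    c("II", "III", "mutation_and_epimutation", "unchanged"),
    c("III", "IV", "ambiguous",                "unchanged"),
    c("III", "I",  "mutation_and_epimutation", "hypomethylation"),
    c("III", "II", "mutation_and_epimutation", "unchanged")
  )
  df <- data.frame(
    from_type = m[, 1], to_type = m[, 2],
    sequence_change = m[, 3], methylation_variation = m[, 4],
    stringsAsFactors = FALSE
  )
  id <- data.frame(
    from_type = BAND_LEVELS, to_type = BAND_LEVELS,
    sequence_change = "none", methylation_variation = "unchanged",
    stringsAsFactors = FALSE
  )
  rbind(df, id)
})

#' The transition classification model as a table
#'
#' All 12 ordered pairs of distinct band types with their sequence-change and
#' methylation-variation verdicts, plus (optionally) the four identity
#' transitions, which classify as no change / unchanged.
#'
#' @param include_identity include the four identity rows (default FALSE).
#' @return data.frame with columns `from_type`, `to_type`, `sequence_change`,
#'   `methylation_variation`.
#' @export
transition_model <- function(include_identity = FALSE) {
  tm <- .transition_model
  if (!include_identity) tm <- tm[tm$from_type != tm$to_type, ]
  rownames(tm) <- NULL
  tm
}

#' Classify a band-type transition
#'
#' Looks up the ordered pair (from, to) in the twelve-transition model.
#' Identity pairs classify as sequence_change `"none"`, methylation_variation
#' `"unchanged"`, so whole matrices can be processed uniformly. Vectorised.
#'
#' @param from_type,to_type band types (`"I".."IV"`, factor or character).
#' @return data.frame with columns `from_type`, `to_type`, `sequence_change`
#'   (one of none, mutation, epimutation, mutation_and_epimutation,
#'   ambiguous) and `methylation_variation` (hypermethylation,
#'   hypomethylation, unchanged).
#' @examples
#' classify_transition("I", "II")    # epimutation, hypermethylation
#' classify_transition("IV", "I")    # mutation, unchanged
#' classify_transition("III", "IV")  # ambiguous, unchanged
#' @export
classify_transition <- function(from_type, to_type) {
  from_type <- as.character(as_band_type(from_type))
  to_type <- as.character(as_band_type(to_type))
  if (length(from_type) != length(to_type))
    stop("from_type and to_type must have equal length", call. = FALSE)
  tm <- .transition_model
  key <- paste(tm$from_type, tm$to_type)
  i <- match(paste(from_type, to_type), key)
  out <- tm[i, ]
  rownames(out) <- NULL
  out
}

#' Round half-up
#'
#' Rounds halves away from zero (for non-negative input, upward), matching
#' how the study's percentages are printed; R's [round()] rounds halves to
#' even.
#'
#' @param x numeric vector (non-negative in this package's use).
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Per-sample band-type counts
#'
#' Constructor/validator for the count vector (n_I, n_II, n_III, n_IV) of a
#' sample's scored loci.
#'
#' @param n_I,n_II,n_III,n_IV non-negative integer counts.
#' @return list of class `band_type_counts` with fields `n_I..n_IV`, `total`.
#' @export
band_type_counts <- function(n_I, n_II, n_III, n_IV) {
  n <- c(n_I = n_I, n_II = n_II, n_III = n_III, n_IV = n_IV)
  if (any(n < 0) || any(n != trunc(n)))
    stop("band-type counts must be non-negative integers", call. = FALSE)
  structure(
    list(n_I = n_I, n_II = n_II, n_III = n_III, n_IV = n_IV,
         total = sum(n)),
    class = "band_type_counts"
  )
}

#' Methylation ratio of a sample
#'
#' The fully-methylated fraction of CpG-informative bands,
#' 100 * nII / (nI + nII), in percent, rounded half-up to 2 decimals. Types
#' III and IV do not enter the ratio. The unmethylated complement is
#' 100 minus the result.
#'
#' @param counts a [band_type_counts()] object, or anything with fields
#'   `n_I` and `n_II` (a one-row data.frame works).
#' @return percentage in `[0, 100]`, 2 decimals.
#' @examples
#' methylation_ratio(band_type_counts(1790, 1994, 813, 841))  # 52.70
#' @export
methylation_ratio <- function(counts) {
  n1 <- counts$n_I
  n2 <- counts$n_II
  if ((n1 + n2) <= 0)
    stop("methylation ratio undefined: no type I or type II bands",
         call. = FALSE)
  round_half_up(100 * n2 / (n1 + n2), 2)
}

#' Write the transition model as TSV
#'
#' Plain-text export of the twelve-transition classification table, for
#' documentation and regression use.
#'
#' @param path output file path.
#' @param include_identity include the identity rows.
#' @return `path`, invisibly.
#' @export
write_transition_model <- function(path, include_identity = FALSE) {
  utils::write.table(transition_model(include_identity), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
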