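#' From raw peaks to the loci x samples band-type matrix
#'
#' The scoring rules follow the assay's reported filters: peaks are kept
#' only with signal height above 1000 RFU and fragment size strictly
#' between 50 and 500 bp; loci are size bins within a primer pair; each
#' sample is coded I-IV from its (MspI lane, HpaII lane) presence pair; and
#' genotype consensus requires the same pattern in at least two of three
#' replicates (total-locus analysis) or in all three (inheritance
#' analysis).
#'
#' @name band-scoring
NULL

#' Filter a peak table
#'
#' Keeps peaks with `height > min_height` and
#' `size_range[1] < size_bp < size_range[2]` (all strict).
#'
#' @param peaks peak table (columns `size_bp`, `height` at least).
#' @param min_height RFU threshold (default 1000).
#' @param size_range bp bounds (default c(50, 500)).
#' @return the filtered peak table; the numbers removed by each filter are
#'   attached as attribute `"filter_log"`.
#' @export
filter_peaks <- function(peaks, min_height = 1000, size_range = c(50, 500)) {
  ok_h <- peaks$height > min_height
  ok_s <- peaks$size_bp > size_range[1] & peaks$size_bp < size_range[2]
  out <- peaks[ok_h & ok_s, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- c(
    input = nrow(peaks),
    removed_height = sum(!ok_h),
    removed_size = sum(ok_h & !ok_s),
    kept = nrow(out)
  )
  out
}

# single-linkage chains split at gaps > tol, then recursively split at the
# largest internal gap while a cluster spans more than 2*tol
split_cluster <- function(sizes, tol) {
  o <- order(sizes)
  s <- sizes[o]
  gaps <- diff(s)
  grp <- cumsum(c(1, as.integer(gaps > tol)))
  refine <- function(ix) {
    if (max(s[ix]) - min(s[ix]) <= 2 * tol || length(ix) < 2) return(list(ix))
    g <- diff(s[ix])
    cut <- which.max(g)
    c(refine(ix[seq_len(cut)]), refine(ix[(cut + 1):length(ix)]))
  }
  parts <- unlist(lapply(split(seq_along(s), grp), refine), recursive = FALSE)
  lab <- integer(length(s))
  for (i in seq_along(parts)) lab[parts[[i]]] <- i
  lab[order(o)]  # back to input order
}

#' Bin filtered peaks into loci
#'
#' Loci are defined within a primer pair only: peak sizes are clustered by
#' single linkage with the given tolerance (chains are kept, so slowly
#' drifting sizes can join one bin), and any cluster wider than twice the
#' tolerance is split at its largest internal gap. Identical sizes in
#' different primer pairs are distinct loci.
#'
#' @param peaks filtered peak table.
#' @param tolerance bp tolerance (default 0.5, typical capillary sizing
#'   precision).
#' @return list of class `msap_bins`: `peaks` (input plus `locus` column)
#'   and `bins` (per locus: `primer_pair`, `size_center`, `size_min`,
#'   `size_max`, `n_peaks`).
#' @export
bin_loci <- function(peaks, tolerance = 0.5) {
  if (nrow(peaks) == 0) {
    return(structure(list(
      peaks = cbind(peaks, locus = character(0)),
      bins = data.frame(locus = character(0), primer_pair = character(0),
                        size_center = numeric(0), size_min = numeric(0),
                        size_max = numeric(0), n_peaks = integer(0))),
      class = "msap_bins"))
  }
  peaks$locus <- NA_character_
  bins <- list()
  for (pp in unique(peaks$primer_pair)) {
    ix <- which(peaks$primer_pair == pp)
    lab <- split_cluster(peaks$size_bp[ix], tolerance)
    for (b in unique(lab)) {
      jx <- ix[lab == b]
      center <- stats::median(peaks$size_bp[jx])
      id <- sprintf("%s@%.1f", pp, center)
      peaks$locus[jx] <- id
      bins[[id]] <- data.frame(
        locus = id, primer_pair = pp, size_center = center,
        size_min = min(peaks$size_bp[jx]), size_max = max(peaks$size_bp[jx]),
        n_peaks = length(jx))
    }
  }
  structure(list(peaks = peaks, bins = do.call(rbind, c(bins, list(make.row.names = FALSE)))),
            class = "msap_bins")
}

#' Code every sample's band type at every locus
#'
#' The locus universe is every bin present in at least one sample x lane
#' after filtering; a locus absent from both lanes of a sample codes IV.
#' Every sample must carry peaks in both lanes of `lane_inventory` (pass
#' the unfiltered peak table there if filtering may empty a lane).
#'
#' @param bins an `msap_bins` from [bin_loci()].
#' @param lane_inventory peak table used to establish which sample x lane
#'   combinations were run; defaults to the binned peaks.
#' @return data.frame of class `msap_matrix`: one row per locus x sample
#'   with columns `locus`, `sample`, `genotype`, `replicate`, `band_type`.
#' @export
code_samples <- function(bins, lane_inventory = NULL) {
  stopifnot(inherits(bins, "msap_bins"))
  pk <- bins$peaks
  inv <- if (is.null(lane_inventory)) pk else lane_inventory
  samples <- unique(inv[, c("sample", "genotype", "replicate")])
  for (i in seq_len(nrow(samples))) {
    lanes <- unique(inv$lane[inv$sample == samples$sample[i]])
    missing <- setdiff(msap_lanes(), lanes)
    if (length(missing))
      stop(sprintf("sample %s is missing lane %s", samples$sample[i],
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  loci <- bins$bins$locus
  grid <- expand.grid(locus = loci, sample = samples$sample,
                      stringsAsFactors = FALSE)
  grid <- merge(grid, samples, by = "sample")
  key <- function(l, s, ln) paste(l, s, ln)
  msp_seen <- unique(key(pk$locus[pk$lane == MSP_LANE],
                         pk$sample[pk$lane == MSP_LANE], "m"))
  hpa_seen <- unique(key(pk$locus[pk$lane == HPA_LANE],
                         pk$sample[pk$lane == HPA_LANE], "h"))
  msp <- key(grid$locus, grid$sample, "m") %in% msp_seen
  hpa <- key(grid$locus, grid$sample, "h") %in% hpa_seen
  grid$band_type <- as.character(code_band_type(msp, hpa))
  grid <- grid[order(grid$locus, grid$sample),
               c("locus", "sample", "genotype", "replicate", "band_type")]
  rownames(grid) <- NULL
  class(grid) <- c("msap_matrix", "data.frame")
  grid
}

#' Wide loci x samples view of a coded matrix
#' @param matrix an `msap_matrix` from [code_samples()].
#' @return data.frame, rows = loci, one column per sample with Roman codes.
#' @export
band_matrix <- function(matrix) {
  w <- stats::reshape(as.data.frame(matrix)[, c("locus", "sample", "band_type")],
                      idvar = "locus", timevar = "sample", direction = "wide")
  names(w) <- sub("^band_type\\.", "", names(w))
  rownames(w) <- NULL
  w
}

#' Genotype consensus across replicates
#'
#' Majority mode keeps the modal band type when it reaches `ceiling(2n/3)`
#' of the n replicates (ties break to excluded); strict mode requires
#' unanimity. Loci that fail the rule in a genotype are marked excluded
#' there.
#'
#' @param matrix an `msap_matrix`.
#' @param mode `"majority_2of3"` or `"strict_identical"`.
#' @return data.frame of class `msap_consensus`: `locus`, `genotype`,
#'   `band_type` (NA when excluded).
#' @export
replicate_consensus <- function(matrix, mode = c("majority_2of3", "strict_identical")) {
  mode <- match.arg(mode)
  df <- as.data.frame(matrix)
  out <- list()
  for (g in unique(df$genotype)) {
    sub <- df[df$genotype == g, ]
    n_rep <- length(unique(sub$replicate))
    if (n_rep < (if (mode == "majority_2of3") 2 else 1))
      stop("fewer replicates than the consensus rule requires", call. = FALSE)
    thr <- ceiling(2 * n_rep / 3)
    cons <- tapply(sub$band_type, sub$locus, function(x) {
      if (length(x) < n_rep) return(NA_character_)
      if (mode == "strict_identical") {
        if (length(unique(x)) == 1) x[1] else NA_character_
      } else {
        tab <- sort(table(x), decreasing = TRUE)
        if (tab[1] >= thr && (length(tab) == 1 || tab[1] > tab[2]))
          names(tab)[1] else NA_character_
      }
    })
    out[[g]] <- data.frame(locus = names(cons), genotype = g,
                           band_type = unname(cons))
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  class(res) <- c("msap_consensus", "data.frame")
  res
}

#' Score a raw peak table end to end
#'
#' Filter, bin, code, and (optionally) build genotype consensus.
#'
#' @param peaks raw peak table.
#' @param min_height,size_range filters, see [filter_peaks()].
#' @param tolerance bin tolerance, see [bin_loci()].
#' @param consensus_mode passed to [replicate_consensus()], or NULL to skip.
#' @return list: `matrix` (`msap_matrix`), `bins`, `consensus` (or NULL),
#'   `filter_log`.
#' @export
score_peak_table <- function(peaks, min_height = 1000, size_range = c(50, 500),
                             tolerance = 0.5, consensus_mode = "majority_2of3") {
  filt <- filter_peaks(peaks, min_height, size_range)
  bins <- bin_loci(filt, tolerance)
  mat <- code_samples(bins, lane_inventory = peaks)
  cons <- if (!is.null(consensus_mode))
    replicate_consensus(mat, consensus_mode) else NULL
  list(matrix = mat, bins = bins, consensus = cons,
       filter_log = attr(filt, "filter_log"))
}

#' Write a loci x samples band-type matrix as TSV
#' @param matrix an `msap_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(matrix, path) {
  utils::write.table(band_matrix(matrix), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
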