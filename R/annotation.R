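#' Genomic feature annotation of changed loci
#'
#' Assigns each locus fragment to a chromosome and a single genic feature
#' class with the precedence promoter > 5'UTR > 3'UTR > exon > intron >
#' intergenic (any overlap counts). Promoters are a fixed strand-aware
#' window upstream of each TSS (default 2 kb). Gene models load from GFF3
#' or BED12; internal coordinates are 0-based half-open, converted at the
#' format boundary by rtracklayer.
#'
#' The 5'UTR class is kept separate so a 5-way split (promoter, exon,
#' intron, 3'UTR, intergenic) can be recovered by merging 5'UTR into exon.
#'
#' @name feature-annotation
NULL

FEATURE_CLASSES <- c("promoter", "five_prime_UTR", "three_prime_UTR",
                     "exon", "intron", "intergenic")

#' Load gene models from GFF3 or BED12
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED12 (`.bed`) file.
#' @param promoter_width promoter window upstream of the TSS, bp.
#' @return list of class `gene_model_index` with GRanges elements `genes`,
#'   `promoters`, `five_utr`, `three_utr`, `exons`, `introns`, each
#'   carrying a `gene_id` column.
#' @export
load_gene_models <- function(path, promoter_width = 2000) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                   error = function(e) stop("malformed GFF3 (", path, "): ",
                                            conditionMessage(e), call. = FALSE))
    if (length(gr) == 0) return(empty_gene_index())
    type <- as.character(gr$type)
    genes <- gr[type == "gene"]
    gene_id <- if (!is.null(genes$ID)) as.character(genes$ID)
               else as.character(seq_along(genes))
    S4Vectors::mcols(genes) <- S4Vectors::DataFrame(gene_id = gene_id)
    pick <- function(t) {
      x <- gr[type == t]
      if (length(x) == 0) {
        S4Vectors::mcols(x) <- S4Vectors::DataFrame(gene_id = character(0))
        return(x)
      }
      par <- as.character(if (!is.null(x$Parent))
        S4Vectors::unstrsplit(as(x$Parent, "CharacterList"), ",") else NA)
      gid <- resolve_gene(par, gr, gene_id)
      S4Vectors::mcols(x) <- S4Vectors::DataFrame(gene_id = gid)
      x
    }
    exons <- pick("exon")
    five <- pick("five_prime_UTR")
    three <- pick("three_prime_UTR")
  } else if (ext == "bed") {
    gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                   error = function(e) stop("malformed BED (", path, "): ",
                                            conditionMessage(e), call. = FALSE))
    if (length(gr) == 0) return(empty_gene_index())
    gene_id <- if (!is.null(gr$name)) as.character(gr$name)
               else as.character(seq_along(gr))
    genes <- gr
    S4Vectors::mcols(genes) <- S4Vectors::DataFrame(gene_id = gene_id)
    if (!is.null(gr$blocks)) {
      bl <- gr$blocks
      exons <- unlist(GenomicRanges::GRangesList(lapply(seq_along(gr), function(i) {
        ab <- IRanges::shift(bl[[i]], GenomicRanges::start(gr)[i] - 1L)
        GenomicRanges::GRanges(GenomicRanges::seqnames(gr)[i], ab,
                               strand = GenomicRanges::strand(gr)[i],
                               gene_id = gene_id[i])
      })))
    } else {
      exons <- genes
    }
    # UTRs from the thick (CDS) interval: exonic sequence outside it
    if (!is.null(gr$thick)) {
      five <- utr_from_thick(gr, exons, gene_id, side = "five")
      three <- utr_from_thick(gr, exons, gene_id, side = "three")
    } else {
      five <- exons[0]
      three <- exons[0]
    }
  } else {
    stop("unsupported gene-model format: .", ext, call. = FALSE)
  }
  introns <- derive_introns(genes, exons)
  proms <- GenomicRanges::promoters(genes, upstream = promoter_width,
                                    downstream = 0)
  # clip windows that fall off the chromosome start
  proms <- GenomicRanges::restrict(proms, start = 1L)
  structure(list(genes = genes, promoters = proms, five_utr = five,
                 three_utr = three, exons = exons, introns = introns,
                 promoter_width = promoter_width),
            class = "gene_model_index")
}

empty_gene_index <- function() {
  g <- GenomicRanges::GRanges()
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(gene_id = character(0))
  structure(list(genes = g, promoters = g, five_utr = g, three_utr = g,
                 exons = g, introns = g, promoter_width = NA),
            class = "gene_model_index")
}

# map Parent attributes (possibly pointing at mRNAs) up to gene IDs
resolve_gene <- function(parent, gr, gene_ids) {
  type <- as.character(gr$type)
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA, length(gr))
  up <- parent
  for (i in 1:3) {
    hit <- match(up, id)
    is_gene <- !is.na(hit) & type[hit] == "gene"
    if (all(is_gene | is.na(hit))) break
    nxt <- ifelse(is_gene | is.na(hit), up, {
      pp <- gr$Parent[hit]
      as.character(S4Vectors::unstrsplit(as(pp, "CharacterList"), ","))
    })
    up <- nxt
  }
  up
}

utr_from_thick <- function(gr, exons, gene_id, side) {
  th <- gr$thick
  out <- list()
  for (i in seq_along(gr)) {
    ex <- exons[exons$gene_id == gene_id[i]]
    if (length(ex) == 0) next
    cds_s <- GenomicRanges::start(th)[i]
    cds_e <- GenomicRanges::end(th)[i]
    minus <- as.character(GenomicRanges::strand(gr))[i] == "-"
    upstream <- (side == "five") != minus  # five' is left of CDS on + strand
    keep <- if (upstream)
      IRanges::restrict(IRanges::ranges(ex), end = cds_s - 1L)
    else
      IRanges::restrict(IRanges::ranges(ex), start = cds_e + 1L)
    keep <- keep[IRanges::width(keep) > 0]
    if (length(keep))
      out[[length(out) + 1]] <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(gr)[i], keep,
        strand = GenomicRanges::strand(gr)[i], gene_id = gene_id[i])
  }
  if (length(out) == 0) {
    g <- exons[0]
    return(g)
  }
  unlist(GenomicRanges::GRangesList(out))
}

derive_introns <- function(genes, exons) {
  if (length(genes) == 0) return(genes[0])
  out <- list()
  for (i in seq_along(genes)) {
    ex <- exons[exons$gene_id == genes$gene_id[i]]
    if (length(ex) == 0) next
    gaps <- GenomicRanges::setdiff(
      GenomicRanges::reduce(genes[i], ignore.strand = TRUE),
      GenomicRanges::reduce(ex, ignore.strand = TRUE), ignore.strand = TRUE)
    if (length(gaps))
      out[[length(out) + 1]] <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(gaps), IRanges::ranges(gaps),
        strand = GenomicRanges::strand(genes)[i],
        gene_id = genes$gene_id[i])
  }
  if (length(out) == 0) return(exons[0])
  unlist(GenomicRanges::GRangesList(out))
}

#' Assign loci to feature classes
#'
#' @param loci GRanges of locus fragments (names or a `locus` column used
#'   as IDs), or a data.frame with `locus`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param index a `gene_model_index`.
#' @return data.frame: `locus`, `chrom`, `start`, `end` (0-based
#'   half-open), `feature`, `gene_id` (NA when intergenic).
#' @export
assign_feature <- function(loci, index) {
  stopifnot(inherits(index, "gene_model_index"))
  if (is.data.frame(loci)) {
    gr <- GenomicRanges::GRanges(
      loci$chrom, IRanges::IRanges(loci$start + 1L, loci$end),
      locus = loci$locus)
  } else {
    gr <- loci
    if (is.null(gr$locus))
      gr$locus <- if (!is.null(names(gr))) names(gr)
                  else as.character(seq_along(gr))
  }
  layers <- list(promoter = index$promoters, five_prime_UTR = index$five_utr,
                 three_prime_UTR = index$three_utr, exon = index$exons,
                 intron = index$introns)
  feature <- rep("intergenic", length(gr))
  gene <- rep(NA_character_, length(gr))
  undecided <- rep(TRUE, length(gr))
  for (cls in names(layers)) {
    lay <- layers[[cls]]
    if (length(lay) == 0) next
    hits <- GenomicRanges::findOverlaps(gr, lay, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    first <- !duplicated(qh)
    sel <- qh[first][undecided[qh[first]]]
    sh <- S4Vectors::subjectHits(hits)[first][undecided[qh[first]]]
    feature[sel] <- cls
    gene[sel] <- as.character(lay$gene_id[sh])
    undecided[sel] <- FALSE
  }
  data.frame(locus = gr$locus,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             feature = factor(feature, levels = FEATURE_CLASSES),
             gene_id = gene)
}

#' Per-chromosome and per-feature distribution of DML classes
#'
#' @param assignments from [assign_feature()].
#' @param labels data.frame with `locus` and `methylation_variation`
#'   (hypermethylation / hypomethylation / unchanged), e.g. the `loci`
#'   element of an [partition_inheritance()] result.
#' @return list: `by_chromosome` and `by_feature` count tables (rows sum to
#'   the annotated loci).
#' @export
distribution_summary <- function(assignments, labels) {
  m <- merge(assignments, labels[, c("locus", "methylation_variation")],
             by = "locus")
  m$methylation_variation[is.na(m$methylation_variation)] <- "unchanged"
  lv <- c("hypermethylation", "hypomethylation", "unchanged")
  m$methylation_variation <- factor(m$methylation_variation, levels = lv)
  list(
    by_chromosome = as.data.frame.matrix(
      table(m$chrom, m$methylation_variation)),
    by_feature = as.data.frame.matrix(
      table(m$feature, m$methylation_variation))
  )
}

#' Locus genomic intervals from a truth table
#'
#' @param truth data.frame from [truth_band_types()].
#' @return GRanges with a `locus` column (1-based closed internally).
#' @export
truth_ranges <- function(truth) {
  GenomicRanges::GRanges(truth$chrom,
                         IRanges::IRanges(truth$start + 1L, truth$end),
                         locus = truth$locus)
}
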