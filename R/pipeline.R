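#' End-to-end pipeline over a simulated cohort
#'
#' One declarative configuration drives simulate -> score -> classify, so a
#' run is reproducible from the config alone. All thresholds default to the
#' assay's reported values: 1000 RFU minimum signal, 50-500 bp sizes,
#' majority (2-of-3) consensus for the total-locus analysis and strict
#' (3-of-3) for the inheritance analysis, alpha = 0.05.
#'
#' @param n_chrom,chrom_length,ccgg_per_kb,ecori_per_kb,nested_fraction
#'   genome parameters, see [generate_genome()].
#' @param meth_fraction base methylome methylated fraction.
#' @param effects a [genotype_effect_config()].
#' @param primers primer panel.
#' @param replicates biological replicates per genotype.
#' @param noise an [msap_noise()].
#' @param min_height,size_range,tolerance scoring parameters.
#' @param alpha t-test significance level.
#' @param seed master seed; stage seeds derive from it.
#' @return list of class `msap_config`.
#' @export
msap_config <- function(n_chrom = 1, chrom_length = 200000, ccgg_per_kb = 2,
                        ecori_per_kb = 2, nested_fraction = 0.2,
                        meth_fraction = 0.55,
                        effects = genotype_effect_config(),
                        primers = primer_panel(1, 2), replicates = 3,
                        noise = msap_noise(), min_height = 1000,
                        size_range = c(50, 500), tolerance = 0.5,
                        alpha = 0.05, seed = 1) {
  structure(as.list(environment()), class = "msap_config")
}

#' Run the full MSAP pipeline on one simulated cohort
#'
#' @param config an [msap_config()].
#' @return list of class `msap_run`:
#'   \describe{
#'     \item{cohort, truth, peaks}{simulation products}
#'     \item{scored}{output of [score_peak_table()] (majority consensus)}
#'     \item{band_counts}{per-sample tallies from [tabulate_band_types()]}
#'     \item{ttests}{pairwise ratio comparisons}
#'     \item{partition, dml}{strict-consensus comparison,
#'       [partition_inheritance()] and [count_dml()] results}
#'   }
#' @export
run_msap_pipeline <- function(config = msap_config()) {
  stopifnot(inherits(config, "msap_config"))
  genome <- generate_genome(config$n_chrom, config$chrom_length,
                            config$ccgg_per_kb, config$ecori_per_kb,
                            config$nested_fraction, seed = config$seed)
  methylome <- generate_methylome(genome, config$meth_fraction,
                                  seed = config$seed + 1)
  cohort <- apply_genotype_effects(genome, methylome, config$effects,
                                   seed = config$seed + 2)
  truth <- truth_band_types(cohort, config$primers, config$size_range)
  peaks <- emit_peak_tables(cohort, config$primers, config$replicates,
                            config$noise, seed = config$seed + 3,
                            size_window = config$size_range)
  scored <- score_peak_table(peaks, config$min_height, config$size_range,
                             config$tolerance, "majority_2of3")
  band_counts <- tabulate_band_types(scored$matrix)
  ttests <- compare_ratio_means(band_counts, alpha = config$alpha)
  strict <- replicate_consensus(scored$matrix, "strict_identical")
  comparison <- compare_to_wildtype(strict)
  partition <- partition_inheritance(comparison)
  dml <- count_dml(partition, n_total = nrow(comparison))
  structure(list(config = config, cohort = cohort, truth = truth,
                 peaks = peaks, scored = scored, band_counts = band_counts,
                 ttests = ttests, comparison = comparison,
                 partition = partition, dml = dml),
            class = "msap_run")
}

#' Bundled reference tables
#'
#' Plain-text copies of the published rat sperm MSAP count tables this
#' package's statistics reproduce:
#' \describe{
#'   \item{"band_counts"}{per-replicate band-type counts (types I-IV) for
#'     the wild-type, transgene-negative and transgene-positive genotypes,
#'     3 biological replicates each, 5438 loci per sample}
#'   \item{"dal_transitions"}{counts of the 12 band-type transitions among
#'     the 1523 changed loci, split by offspring sharing (only-negative /
#'     only-positive / both)}
#' }
#'
#' @param name one of `"band_counts"`, `"dal_transitions"`.
#' @return data.frame.
#' @export
msap_reference_table <- function(name = c("band_counts", "dal_transitions")) {
  name <- match.arg(name)
  f <- system.file("extdata", paste0(name, ".tsv"), package = "epimsap",
                   mustWork = TRUE)
  utils::read.delim(f, stringsAsFactors = FALSE)
}
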