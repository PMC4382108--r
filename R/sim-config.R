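#' Configuration for the synthetic F1 cross generator
#'
#' Defines the study conditions emulated by [simulate_cross()]: a two-parent
#' outbred cross genotyped by targeted capture sequencing. Defaults describe a
#' cross of 149 offspring over 18 chromosomes — the design of capture-based
#' linkage mapping in rubber tree — with a realistic mix of pseudo-testcross
#' segregation types.
#'
#' @param n_chromosomes number of chromosomes (default 18).
#' @param chrom_length chromosome genetic length in cM (default 120).
#' @param n_offspring number of F1 offspring genotyped (default 149; the two
#'   parents are always genotyped in addition).
#' @param markers_per_chromosome markers simulated per chromosome (default 50).
#' @param cross_type_mix proportions of the four segregation types, in order
#'   P1-het 1:1 (`ab x aa`), P2-het 1:1 (`aa x ab`), both-het 1:2:1 (`ab x ab`),
#'   fully informative 1:1:1:1 (`ab x cd`). Must sum to 1.
#' @param mean_depth mean per-call read depth (reads).
#' @param depth_dispersion negative-binomial size parameter for per-call depth;
#'   smaller values give more over-dispersed depth, as seen in capture data.
#' @param error_rate per-call probability that the observed genotype is replaced
#'   by a different genotype from the locus's genotype space.
#' @param missing_rate per-call probability of a no-call.
#' @param distorted_fraction proportion of loci with skewed transmission.
#' @param distortion_skew transmission probability of the favoured allele at a
#'   distorted locus (default 0.8; 0.5 means no distortion).
#' @param repeat_dup_fraction proportion of multi-marker contigs whose markers
#'   are split between two distinct true map locations, emulating collapsed
#'   repeat sequence in the assembly.
#' @param contigs_per_scaffold mean number of contigs per scaffold; scaffold
#'   sizes are drawn as `1 + Poisson(contigs_per_scaffold - 1)`.
#' @param n_snpless_ref_scaffolds number of extra scaffolds carrying a
#'   reference-map (microsatellite-style) anchor but no SNP marker, used to
#'   exercise reference-only scaffold integration.
#' @param seed integer seed; identical seeds give bit-identical fixtures.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [simulate_cross()], [sample_observed_calls()], [write_fixture()]
#' @export
sim_config <- function(n_chromosomes = 18,
                       chrom_length = 120,
                       n_offspring = 149,
                       markers_per_chromosome = 50,
                       cross_type_mix = c(p1_het = 0.2, p2_het = 0.2,
                                          both_het = 0.3, fully_informative = 0.3),
                       mean_depth = 60,
                       depth_dispersion = 5,
                       error_rate = 0.005,
                       missing_rate = 0.03,
                       distorted_fraction = 0.02,
                       distortion_skew = 0.8,
                       repeat_dup_fraction = 0.01,
                       contigs_per_scaffold = 3,
                       n_snpless_ref_scaffolds = 10,
                       seed = 1L) {
  check_num(n_chromosomes, "n_chromosomes", 1, Inf, integer = TRUE)
  check_num(chrom_length, "chrom_length", 1e-6, Inf)
  check_num(n_offspring, "n_offspring", 2, Inf, integer = TRUE)
  check_num(markers_per_chromosome, "markers_per_chromosome", 2, Inf, integer = TRUE)
  am_check(is.numeric(cross_type_mix) && length(cross_type_mix) == 4L &&
             all(is.finite(cross_type_mix)) && all(cross_type_mix >= 0) &&
             all(cross_type_mix <= 1),
           "'cross_type_mix' must be 4 proportions in [0,1]")
  am_check(abs(sum(cross_type_mix) - 1) < 1e-8, "'cross_type_mix' must sum to 1")
  check_num(mean_depth, "mean_depth", 0, Inf)
  check_num(depth_dispersion, "depth_dispersion", 1e-6, Inf)
  check_num(error_rate, "error_rate", 0, 1)
  check_num(missing_rate, "missing_rate", 0, 1)
  check_num(distorted_fraction, "distorted_fraction", 0, 1)
  check_num(distortion_skew, "distortion_skew", 0, 1)
  check_num(repeat_dup_fraction, "repeat_dup_fraction", 0, 1)
  check_num(contigs_per_scaffold, "contigs_per_scaffold", 1, Inf)
  check_num(n_snpless_ref_scaffolds, "n_snpless_ref_scaffolds", 0, Inf, integer = TRUE)
  check_num(seed, "seed", -2^31, 2^31, integer = TRUE)

  names(cross_type_mix) <- c("p1_het", "p2_het", "both_het", "fully_informative")
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length,
              n_offspring = as.integer(n_offspring),
              markers_per_chromosome = as.integer(markers_per_chromosome),
              cross_type_mix = cross_type_mix,
              mean_depth = mean_depth,
              depth_dispersion = depth_dispersion,
              error_rate = error_rate,
              missing_rate = missing_rate,
              distorted_fraction = distorted_fraction,
              distortion_skew = distortion_skew,
              repeat_dup_fraction = repeat_dup_fraction,
              contigs_per_scaffold = contigs_per_scaffold,
              n_snpless_ref_scaffolds = as.integer(n_snpless_ref_scaffolds),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic F1 cross configuration\n")
  cat(sprintf("  %d chromosomes x %g cM, %d markers each; %d offspring (+2 parents)\n",
              x$n_chromosomes, x$chrom_length, x$markers_per_chromosome, x$n_offspring))
  cat(sprintf("  segregation mix (lmxll/nnxnp/hkxhk/abxcd): %s\n",
              paste(format(x$cross_type_mix), collapse = " / ")))
  cat(sprintf("  depth NB(mu=%g, size=%g); error %g; missing %g\n",
              x$mean_depth, x$depth_dispersion, x$error_rate, x$missing_rate))
  cat(sprintf("  distorted %g (skew %g); repeat-dup contigs %g; seed %d\n",
              x$distorted_fraction, x$distortion_skew, x$repeat_dup_fraction, x$seed))
  invisible(x)
}
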