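#' Configuration for the synthetic study generator
#'
#' Describes a synthetic resequencing study of clonal aphid lines: a set of
#' genomic scaffolds with hidden X/autosome identities, a panel of diploid
#' clonal lines carrying neutral polymorphism, and per-line winged/wingless
#' brother males sequenced at a chosen depth. Defaults emulate the study
#' design this package targets: ~12% of scaffold length X-linked, diversity
#' theta = 0.005/bp, 21 lines, a single high-coverage focal line whose
#' brother males drive X assignment, and a low-coverage panel whose merged
#' male data average roughly 5-6 lines represented per base pair.
#'
#' Males are diploid for autosomes but carry a single X, so X-linked
#' positions receive half the autosomal read depth. Each read base is
#' correct with probability `1 - error_rate`, otherwise a uniformly chosen
#' different base; read qualities take one of two Phred values straddling
#' the Q20 filter so the quality cutoff is exercised deterministically.
#'
#' @param n_scaffolds Number of scaffolds.
#' @param scaffold_length Length-2 numeric range (bp); scaffold lengths are
#'   drawn uniformly from it. A single value fixes all lengths.
#' @param x_fraction Probability that a scaffold is X-linked; the X share of
#'   total length then matches this fraction up to sampling error.
#' @param theta Scaled per-bp mutation rate (target pairwise diversity).
#' @param n_lines Number of diploid clonal lines (each contributes a
#'   winged and a wingless male sample).
#' @param depth_focal_male Mean read depth per autosomal bp for each male of
#'   the focal (high-coverage) line.
#' @param depth_panel_male Mean read depth per autosomal bp for each male of
#'   every other line. The default 0.2 gives, after merging a line's two
#'   males and quality filtering, about 5-6 lines represented per bp.
#' @param error_rate Per-base sequencing error probability.
#' @param qual_high,qual_low The two Phred qualities emitted; they must
#'   straddle the Q20 consensus filter.
#' @param prop_high_qual Probability a read base carries `qual_high`.
#' @param chimera_fraction Fraction of scaffolds that are chimeric
#'   misassemblies joining an X-linked and an autosomal segment at a single
#'   breakpoint.
#' @param gene_spacing Approximate distance between gene starts (bp).
#' @param seed Optional integer seed stored with the configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_scaffolds = 1000,
                       scaffold_length = c(1e5, 3e5),
                       x_fraction = 0.12,
                       theta = 0.005,
                       n_lines = 21,
                       depth_focal_male = 9,
                       depth_panel_male = 0.2,
                       error_rate = 1e-3,
                       qual_high = 30L,
                       qual_low = 15L,
                       prop_high_qual = 0.8,
                       chimera_fraction = 0,
                       gene_spacing = 15000,
                       seed = NULL) {
  if (n_scaffolds < 1) stop_config("`n_scaffolds` must be at least 1")
  if (any(scaffold_length <= 0)) stop_config("scaffold lengths must be positive")
  if (x_fraction < 0 || x_fraction > 1) stop_config("`x_fraction` must lie in [0, 1]")
  if (theta < 0) stop_config("`theta` must be non-negative")
  if (n_lines < 1) stop_config("`n_lines` must be at least 1")
  if (depth_focal_male <= 0 || depth_panel_male <= 0) {
    stop_config("male read depths must be positive")
  }
  if (error_rate < 0 || error_rate >= 1) stop_config("`error_rate` must lie in [0, 1)")
  if (!(qual_low <= 20 && qual_high > 20)) {
    stop_config("`qual_low` must be <= 20 and `qual_high` > 20 so that the Q20 filter separates them")
  }
  if (chimera_fraction < 0 || chimera_fraction > 1) {
    stop_config("`chimera_fraction` must lie in [0, 1]")
  }
  if (length(scaffold_length) == 1L) scaffold_length <- rep(scaffold_length, 2L)
  structure(
    list(
      n_scaffolds = as.integer(n_scaffolds),
      scaffold_length = as.numeric(scaffold_length),
      x_fraction = x_fraction,
      theta = theta,
      n_lines = as.integer(n_lines),
      depth_focal_male = depth_focal_male,
      depth_panel_male = depth_panel_male,
      error_rate = error_rate,
      qual_high = as.integer(qual_high),
      qual_low = as.integer(qual_low),
      prop_high_qual = prop_high_qual,
      chimera_fraction = chimera_fraction,
      gene_spacing = gene_spacing,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  scaffolds: %d (%g-%g bp), X fraction %.3g, chimeras %.3g\n",
              x$n_scaffolds, x$scaffold_length[1], x$scaffold_length[2],
              x$x_fraction, x$chimera_fraction))
  cat(sprintf("  lines: %d, theta = %g/bp\n", x$n_lines, x$theta))
  cat(sprintf("  depth/male: focal %g, panel %g; error %g; quals %d/%d (P[high] = %g)\n",
              x$depth_focal_male, x$depth_panel_male, x$error_rate,
              x$qual_high, x$qual_low, x$prop_high_qual))
  invisible(x)
}

#' Configuration for the forward life-cycle simulator
#'
#' Parameters of a forward population simulation of cyclical parthenogenesis
#' with X0 male determination: several clonal (parthenogenetic) generations
#' per year followed by one sexual generation in which males arise by random
#' loss of one maternal X chromosome and every sperm carries the male's X.
#'
#' @param n_females Census number of females.
#' @param parth_gens_per_year Parthenogenetic generations preceding each
#'   sexual generation. Zero gives an ordinary obligately sexual population.
#' @param n_years Number of annual cycles to run.
#' @param mu Per-locus, per-generation mutation rate (infinite alleles).
#' @param n_loci_x,n_loci_a Numbers of X-linked and autosomal marker loci.
#' @param burn_in_years Years discarded before diversity is recorded.
#' @param seed Optional integer seed stored with the configuration.
#' @return A `life_cycle_config` list.
#' @export
life_cycle_config <- function(n_females = 200,
                              parth_gens_per_year = 5,
                              n_years = 80,
                              mu = 1e-3,
                              n_loci_x = 20,
                              n_loci_a = 20,
                              burn_in_years = NULL,
                              seed = NULL) {
  if (n_females < 1) stop_config("`n_females` must be at least 1")
  if (parth_gens_per_year < 0) stop_config("`parth_gens_per_year` must be >= 0")
  if (n_years < 1) stop_config("`n_years` must be at least 1")
  if (mu < 0 || mu > 1) stop_config("`mu` must lie in [0, 1]")
  if (n_loci_x < 1 || n_loci_a < 1) stop_config("locus counts must be at least 1")
  burn_in_years <- burn_in_years %||% floor(n_years * 0.75)
  if (burn_in_years >= n_years) stop_config("`burn_in_years` must be smaller than `n_years`")
  structure(
    list(
      n_females = as.integer(n_females),
      parth_gens_per_year = as.integer(parth_gens_per_year),
      n_years = as.integer(n_years),
      mu = mu,
      n_loci_x = as.integer(n_loci_x),
      n_loci_a = as.integer(n_loci_a),
      burn_in_years = as.integer(burn_in_years),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "life_cycle_config"
  )
}
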