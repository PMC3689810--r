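#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rpois rbinom runif rhyper median mad optimize dt setNames
#'   quantile sd wilcox.test rt complete.cases
#' @importFrom utils head tail
NULL

BASES <- c("A", "C", "G", "T")

#' Derive a reproducible sub-seed for a pipeline stage
#'
#' All randomness in the package flows from a single user seed. Each stage
#' (reference, genotypes, per-sample sequencing, mixture restarts, ...)
#' draws from its own stream, derived deterministically from the master seed
#' and a small stream index, so that adding a stage never perturbs the
#' draws of another.
#'
#' @param seed Integer master seed.
#' @param stream Small non-negative integer identifying the consumer.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # affine map over a Mersenne-prime modulus; exact in double precision
  as.integer((abs(seed) * 48271 + 16807 * (stream + 1)) %% 2147483647)
}

# run code under a temporary seed without clobbering the caller's RNG state
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

random_dna <- function(n) {
  sample(BASES, n, replace = TRUE)
}

# complement of A/C/G/T; N and missing pass through
comp_base <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")
  unname(map[x])
}

revcomp_chars <- function(x) rev(comp_base(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# standard genetic code, from Biostrings
SENSE_CODON_CHARS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]

translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

stop_input <- function(msg) abort(msg, class = "aphidpop_input_error")
stop_config <- function(msg) abort(msg, class = "aphidpop_config_error")
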