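#' Forward simulation of cyclical parthenogenesis with X0 males
#'
#' Simulates a population of females through repeated annual cycles:
#' several parthenogenetic generations in which each daughter is an exact
#' copy of a randomly chosen mother (plus mutation), followed by one sexual
#' generation.  In the sexual generation males are produced asexually and
#' are genetically identical to their mothers except that each male has
#' randomly lost one maternal X chromosome (all X-linked loci lose the same
#' copy: there is no recombination in male production).  Every viable sperm
#' carries the male's X, and a sexual female transmits one of her two X
#' copies per gamete, so all fertilized eggs are XX females.  Because both
#' sexes always transmit an X, the X chromosome and the autosomes are
#' expected to hold essentially equal neutral diversity (the 1:1 X:A
#' expectation), unlike XX/XY or standard XX/X0 systems.
#'
#' Loci are unlinked across chromosomes and follow the infinite-alleles
#' model: every mutation creates a novel allele.  Diversity pi per locus is
#' the sample-size-corrected probability that two gene copies drawn from
#' the females differ, `2N/(2N - 1) * (1 - sum(p^2))`.
#'
#' @param config A [life_cycle_config()].
#' @param seed Integer seed.
#' @return A `life_cycle_sim` list: `trajectory` (tibble: year, chromosome,
#'   mean pi over loci, recorded after burn-in) and `summary` (one-row
#'   tibble: pi_x, pi_a, their ratio, and the numbers of loci and recorded
#'   years).
#' @export
simulate_life_cycle <- function(config, seed = NULL) {
  stopifnot(inherits(config, "life_cycle_config"))
  seed <- seed %||% config$seed %||% 1L
  N <- config$n_females
  if (N < 1) stop_input("population is extinct: `n_females` must be positive")
  Kx <- config$n_loci_x
  Ka <- config$n_loci_a

  local_seed(derive_seed(seed, 4L), {
    # allele-id matrices: N females x 2 copies, one per locus
    X <- replicate(Kx, matrix(1L, N, 2), simplify = FALSE)
    A <- replicate(Ka, matrix(1L, N, 2), simplify = FALSE)
    next_allele <- rep(2L, Kx + Ka)

    mutate_all <- function() {
      for (k in seq_len(Kx)) {
        n_mut <- rpois(1, config$mu * 2 * N)
        if (n_mut > 0) {
          idx <- sample.int(2L * N, min(n_mut, 2L * N))
          X[[k]][idx] <<- next_allele[k] + seq_along(idx) - 1L
          next_allele[k] <<- next_allele[k] + length(idx)
        }
      }
      for (k in seq_len(Ka)) {
        n_mut <- rpois(1, config$mu * 2 * N)
        if (n_mut > 0) {
          idx <- sample.int(2L * N, min(n_mut, 2L * N))
          A[[k]][idx] <<- next_allele[Kx + k] + seq_along(idx) - 1L
          next_allele[Kx + k] <<- next_allele[Kx + k] + length(idx)
        }
      }
    }

    pi_mean <- function(mats) {
      mean(vapply(mats, function(m) {
        n <- length(m)
        p <- tabulate(match(m, unique(as.vector(m)))) / n
        n / (n - 1) * (1 - sum(p^2))
      }, 0))
    }

    traj <- list()
    for (year in seq_len(config$n_years)) {
      for (g in seq_len(config$parth_gens_per_year)) {
        mothers <- sample.int(N, N, replace = TRUE)
        for (k in seq_len(Kx)) X[[k]] <- X[[k]][mothers, , drop = FALSE]
        for (k in seq_len(Ka)) A[[k]] <- A[[k]][mothers, , drop = FALSE]
        mutate_all()
      }
      # males: each female contributes one male, a clone of his mother
      # missing one of her X chromosomes
      male_mothers <- sample.int(N, N, replace = FALSE)
      male_kept <- sample(1:2, N, replace = TRUE)
      male_X <- purrr::map(X, function(m) m[cbind(male_mothers, male_kept)])
      male_A <- purrr::map(A, function(m) m[male_mothers, , drop = FALSE])
      # mating: each egg takes a maternal gamete and a sperm; sperm always
      # carry the sire's X, so offspring are XX females
      dams <- sample.int(N, N, replace = TRUE)
      sires <- sample.int(N, N, replace = TRUE)
      for (k in seq_len(Kx)) {
        maternal <- X[[k]][cbind(dams, sample(1:2, N, replace = TRUE))]
        X[[k]] <- cbind(maternal, male_X[[k]][sires])
      }
      for (k in seq_len(Ka)) {
        maternal <- A[[k]][cbind(dams, sample(1:2, N, replace = TRUE))]
        paternal <- male_A[[k]][cbind(sires, sample(1:2, N, replace = TRUE))]
        A[[k]] <- cbind(maternal, paternal)
      }
      mutate_all()

      if (year > config$burn_in_years) {
        traj[[length(traj) + 1L]] <- tibble(
          year = year,
          chromosome = c("X", "A"),
          pi = c(pi_mean(X), pi_mean(A))
        )
      }
    }
    trajectory <- dplyr::bind_rows(traj)
    wide <- trajectory |>
      dplyr::group_by(.data$chromosome) |>
      dplyr::summarise(pi = mean(.data$pi), .groups = "drop")
    pi_x <- wide$pi[wide$chromosome == "X"]
    pi_a <- wide$pi[wide$chromosome == "A"]
    structure(
      list(
        trajectory = trajectory,
        summary = tibble(pi_x = pi_x, pi_a = pi_a,
                         ratio = ifelse(pi_a > 0, pi_x / pi_a, NA_real_),
                         n_loci_x = Kx, n_loci_a = Ka,
                         years_recorded = config$n_years - config$burn_in_years),
        config = config, seed = seed
      ),
      class = "life_cycle_sim"
    )
  })
}

#' @export
print.life_cycle_sim <- function(x, ...) {
  cat(sprintf("<life_cycle_sim> N = %d females, %d years (%d recorded)\n",
              x$config$n_females, x$config$n_years,
              x$summary$years_recorded))
  cat(sprintf("  pi_X = %.4g, pi_A = %.4g, X:A ratio = %.3f\n",
              x$summary$pi_x, x$summary$pi_a, x$summary$ratio))
  invisible(x)
}
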