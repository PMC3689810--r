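#' Per-site valid-allele counts of an alignment
#'
#' Counts A/C/G/T calls per column; `N` and missing (`-`, `NA`) calls are
#' excluded everywhere downstream.
#'
#' @param aln Character matrix (rows = sequences, columns = sites) over
#'   `A,C,G,T,N,-`.
#' @return Integer matrix (sites x 4) with columns A, C, G, T.
#' @export
allele_counts <- function(aln) {
  if (is.matrix(aln)) {
    counts <- vapply(BASES, function(b) {
      as.integer(colSums(aln == b, na.rm = TRUE))
    }, integer(ncol(aln)))
    if (ncol(aln) == 1L) counts <- matrix(counts, 1L, 4L)
  } else {
    stop_input("`aln` must be a character matrix")
  }
  colnames(counts) <- BASES
  counts
}

harmonic_number <- function(n) {
  # a1(n) = sum_{k=1}^{n-1} 1/k, the Watterson sample-size correction
  vapply(n, function(m) if (m < 2) NA_real_ else sum(1 / seq_len(m - 1L)), 0)
}

#' Tajima (1989) variance constants
#'
#' @param n Sample size (number of sequences).
#' @return A list with a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  if (n < 2) stop_input("Tajima constants require n >= 2")
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Segregating sites of an alignment
#'
#' A site segregates when at least two distinct valid (non-N, non-missing)
#' alleles are observed.  Sites with fewer than two valid alleles carry no
#' information and are excluded from the valid-length denominator.
#'
#' @param aln Character matrix, or a counts matrix from [allele_counts()].
#' @return A list with `S`, the logical per-site vector `segregating`, the
#'   per-site valid-allele count `n_valid`, and `L_valid`.
#' @export
segregating_sites <- function(aln) {
  counts <- if (is.matrix(aln) && is.numeric(aln)) aln else allele_counts(aln)
  n_valid <- rowSums(counts)
  n_alleles <- rowSums(counts > 0)
  segregating <- n_alleles >= 2
  list(S = sum(segregating), segregating = segregating,
       n_valid = n_valid, L_valid = sum(n_valid >= 2))
}

# per-site heterozygosity h_i = n/(n-1) * (1 - sum p^2), 0 where n < 2
.site_het <- function(counts, n_valid) {
  h <- numeric(nrow(counts))
  ok <- n_valid >= 2
  if (any(ok)) {
    p2 <- rowSums((counts[ok, , drop = FALSE] / n_valid[ok])^2)
    h[ok] <- n_valid[ok] / (n_valid[ok] - 1) * (1 - p2)
  }
  h
}

#' Diversity statistics for one region alignment
#'
#' Computes the segregating-site count S, Watterson's theta and nucleotide
#' diversity pi per valid bp, and Tajima's D.  Sample size varies by site
#' (missing data are common in low-coverage consensus data), so theta and pi
#' apply the sample-size correction per site:
#' `theta_w = sum_i s_i / a1(n_i) / L_valid` and `pi = sum_i h_i / L_valid`,
#' where `n_i` is the number of valid alleles at site i and `L_valid` counts
#' sites with `n_i >= 2`.  Tajima's D uses the 1989 variance constants
#' evaluated at a single effective sample size, the rounded mean `n_i` over
#' segregating sites, with the region's summed (not per-bp) pi and theta.
#'
#' Undefined statistics are returned as `NA` (never 0): D is `NA` when
#' `S = 0`, when the effective sample size is below 4, or when the variance
#' term is non-positive; all statistics are `NA` when `L_valid = 0`.
#'
#' @param aln Character matrix, or counts matrix from [allele_counts()].
#' @param region_id Optional identifier copied into the result.
#' @return One-row tibble: region_id, L, L_valid, S, theta_w, pi, tajimas_d,
#'   n_eff, coverage (mean valid alleles per bp over all sites).
#' @export
diversity_stats <- function(aln, region_id = NA_character_) {
  counts <- if (is.matrix(aln) && is.numeric(aln)) aln else allele_counts(aln)
  L <- nrow(counts)
  seg <- segregating_sites(counts)
  n_valid <- seg$n_valid
  L_valid <- seg$L_valid
  coverage <- if (L > 0) mean(n_valid) else NA_real_
  if (L == 0 || L_valid == 0) {
    return(tibble(region_id = region_id, L = L, L_valid = L_valid,
                  S = if (L == 0) NA_integer_ else 0L,
                  theta_w = NA_real_, pi = NA_real_, tajimas_d = NA_real_,
                  n_eff = NA_integer_, coverage = coverage))
  }
  h <- .site_het(counts, n_valid)
  pi_total <- sum(h)
  s_i <- seg$segregating
  theta_site <- numeric(L)
  informative <- n_valid >= 2
  theta_site[s_i] <- 1 / harmonic_number(n_valid[s_i])
  theta_total <- sum(theta_site)
  S <- seg$S

  n_eff <- if (S > 0) as.integer(round(mean(n_valid[s_i]))) else NA_integer_
  D <- NA_real_
  if (S > 0 && !is.na(n_eff) && n_eff >= 4) {
    k <- tajima_constants(n_eff)
    v <- k$e1 * S + k$e2 * S * (S - 1)
    if (v > 0) D <- (pi_total - theta_total) / sqrt(v)
  }
  tibble(region_id = region_id, L = L, L_valid = L_valid, S = as.integer(S),
         theta_w = theta_total / L_valid, pi = pi_total / L_valid,
         tajimas_d = D, n_eff = n_eff, coverage = coverage)
}

#' Hudson-style Fst between two populations
#'
#' `Fst = 1 - Hw / Hb`, with `Hw` the mean of the two within-population
#' per-site diversities and `Hb` the mean between-population pairwise
#' difference per bp, each summed over sites before the ratio
#' (ratio of sums).  The estimator admits small negative values under
#' panmixia.  Sites require at least two valid alleles in each population.
#' A Weir-Cockerham estimator (1984 variance components, treating the
#' pseudo-haploid consensus calls as haploid samples) is available as a
#' cross-check via `method = "wc"`.
#'
#' @param aln1,aln2 Character matrices (or counts matrices) for the two
#'   populations over the same sites.
#' @param method `"hudson"` (default) or `"wc"`.
#' @return One-row tibble: fst, hw, hb, L_valid.
#' @export
fst <- function(aln1, aln2, method = c("hudson", "wc")) {
  method <- match.arg(method)
  c1 <- if (is.matrix(aln1) && is.numeric(aln1)) aln1 else allele_counts(aln1)
  c2 <- if (is.matrix(aln2) && is.numeric(aln2)) aln2 else allele_counts(aln2)
  if (nrow(c1) != nrow(c2)) stop_input("alignments cover different site sets")
  n1 <- rowSums(c1)
  n2 <- rowSums(c2)
  ok <- n1 >= 2 & n2 >= 2
  L_valid <- sum(ok)
  if (L_valid == 0) {
    return(tibble(fst = NA_real_, hw = NA_real_, hb = NA_real_, L_valid = 0L))
  }
  c1 <- c1[ok, , drop = FALSE]; c2 <- c2[ok, , drop = FALSE]
  n1 <- n1[ok]; n2 <- n2[ok]
  h1 <- .site_het(c1, n1)
  h2 <- .site_het(c2, n2)
  hb_site <- 1 - rowSums((c1 / n1) * (c2 / n2))
  hw <- (sum(h1) + sum(h2)) / 2 / L_valid
  hb <- sum(hb_site) / L_valid
  if (method == "hudson") {
    f <- if (hb > 0) 1 - hw / hb else NA_real_
    return(tibble(fst = f, hw = hw, hb = hb, L_valid = as.integer(L_valid)))
  }
  # Weir-Cockerham (haploid samples, two populations), ratio of sums
  p1 <- c1 / n1
  p2 <- c2 / n2
  nbar <- (n1 + n2) / 2
  r <- 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  num <- 0; den <- 0
  for (a in 1:4) {
    pbar <- (n1 * p1[, a] + n2 * p2[, a]) / (r * nbar)
    s2 <- (n1 * (p1[, a] - pbar)^2 + n2 * (p2[, a] - pbar)^2) / ((r - 1) * nbar)
    msp <- s2
    msg <- (n1 * p1[, a] * (1 - p1[, a]) + n2 * p2[, a] * (1 - p2[, a])) /
      (n1 + n2 - r)
    num <- num + sum(msp - msg)
    den <- den + sum(msp + (nc - 1) * msg)
  }
  f <- if (den > 0) num / den else NA_real_
  tibble(fst = f, hw = hw, hb = hb, L_valid = as.integer(L_valid))
}

#' Keep regions with enough polymorphism
#'
#' Retains regions with at least `min_S` segregating sites ("at least"
#' is inclusive: `S = 50` is kept at the default cutoff).
#'
#' @param stats Tibble with an `S` column (e.g. rows from
#'   [diversity_stats()]).
#' @param min_S Minimum segregating-site count.
#' @return The retained subset.
#' @export
polymorphism_filter <- function(stats, min_S = 50) {
  dplyr::filter(stats, !is.na(.data$S), .data$S >= min_S)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midrank tie handling: exact enumeration for small
#' tie-free samples (both groups of 20 or fewer), otherwise the normal
#' approximation with the tie correction.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return One-row tibble: `u` (U statistic for `x`), `p` (two-sided).
#' @export
mw_test <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0) {
    stop_input("both groups must contain finite values")
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- !has_ties && length(x) <= 20 && length(y) <= 20
  res <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = !exact)
  )
  tibble(u = unname(res$statistic), p = res$p.value,
         n_x = length(x), n_y = length(y))
}
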