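# Independent brute-force implementations of the diversity statistics,
# used as oracles: direct pair counting and direct site loops, no shared
# code with the package internals.

oracle_valid <- function(col) col[col %in% c("A", "C", "G", "T")]

# S, theta_w, pi (per valid bp) and Tajima's D by explicit loops
oracle_stats <- function(aln) {
  L <- ncol(aln)
  S <- 0L
  L_valid <- 0L
  pi_total <- 0
  theta_total <- 0
  n_seg <- integer(0)
  for (j in seq_len(L)) {
    v <- oracle_valid(aln[, j])
    ni <- length(v)
    if (ni < 2) next
    L_valid <- L_valid + 1L
    diff <- 0L
    pairs <- 0L
    for (a in 1:(ni - 1)) {
      for (b in (a + 1):ni) {
        pairs <- pairs + 1L
        if (v[a] != v[b]) diff <- diff + 1L
      }
    }
    pi_total <- pi_total + diff / pairs
    if (length(unique(v)) >= 2) {
      S <- S + 1L
      theta_total <- theta_total + 1 / sum(1 / seq_len(ni - 1))
      n_seg <- c(n_seg, ni)
    }
  }
  D <- NA_real_
  n_eff <- if (S > 0) round(mean(n_seg)) else NA
  if (S > 0 && !is.na(n_eff) && n_eff >= 4) {
    n <- n_eff
    a1 <- sum(1 / seq_len(n - 1))
    a2 <- sum(1 / seq_len(n - 1)^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    vr <- (c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1)
    if (vr > 0) D <- (pi_total - theta_total) / sqrt(vr)
  }
  list(S = S, L_valid = L_valid,
       theta_w = if (L_valid > 0) theta_total / L_valid else NA_real_,
       pi = if (L_valid > 0) pi_total / L_valid else NA_real_,
       tajimas_d = D, n_eff = n_eff)
}

# Hudson Fst by explicit pair counting
oracle_fst <- function(aln1, aln2) {
  L <- ncol(aln1)
  hw_total <- 0
  hb_total <- 0
  L_valid <- 0L
  pair_diff_frac <- function(v) {
    ni <- length(v)
    diff <- 0L
    pairs <- 0L
    for (a in 1:(ni - 1)) for (b in (a + 1):ni) {
      pairs <- pairs + 1L
      if (v[a] != v[b]) diff <- diff + 1L
    }
    diff / pairs
  }
  for (j in seq_len(L)) {
    v1 <- oracle_valid(aln1[, j])
    v2 <- oracle_valid(aln2[, j])
    if (length(v1) < 2 || length(v2) < 2) next
    L_valid <- L_valid + 1L
    hw_total <- hw_total + (pair_diff_frac(v1) + pair_diff_frac(v2)) / 2
    diff <- 0L
    for (a in seq_along(v1)) for (b in seq_along(v2)) {
      if (v1[a] != v2[b]) diff <- diff + 1L
    }
    hb_total <- hb_total + diff / (length(v1) * length(v2))
  }
  if (L_valid == 0 || hb_total == 0) return(NA_real_)
  1 - hw_total / hb_total
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v)
  ranks <- rank(all_v)
  u_of <- function(idx) {
    sum(ranks[idx]) - length(idx) * (length(idx) + 1) / 2
  }
  u_obs <- u_of(seq_along(x))
  mu <- length(x) * length(y) / 2
  combos <- utils::combn(n, length(x))
  us <- apply(combos, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# random alignment with missing data and ambiguities
random_alignment <- function(n_seq, L, miss = 0.1, amb = 0.05, n_alleles = 2) {
  aln <- matrix(sample(c("A", "C", "G", "T")[seq_len(n_alleles)],
                       n_seq * L, replace = TRUE), n_seq, L)
  drop <- matrix(runif(n_seq * L) < miss, n_seq, L)
  aln[drop] <- "-"
  nn <- matrix(runif(n_seq * L) < amb, n_seq, L)
  aln[nn] <- "N"
  aln
}
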