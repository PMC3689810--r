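test_that("theta and pi match hand-evaluated closed forms", {
  # 4 sequences, 100 sites, 3 biallelic segregating sites (3:1), no missing
  counts <- matrix(0L, 100, 4)
  counts[, 1] <- 4L
  counts[1:3, 1] <- 3L
  counts[1:3, 2] <- 1L
  st <- diversity_stats(counts)
  a4 <- 1 + 1 / 2 + 1 / 3
  expect_equal(st$S, 3L)
  expect_equal(st$theta_w, 3 / (a4 * 100), tolerance = 1e-12)
  # per-site heterozygosity for counts 3:1 is (4/3) * (1 - 10/16) = 0.5
  expect_equal(st$pi, 3 * 0.5 / 100, tolerance = 1e-12)

  # one site with counts A:2, G:2 has h = (4/3)(1 - 1/4 - 1/4) = 2/3
  one <- matrix(c(2L, 0L, 2L, 0L), 1, 4)
  expect_equal(diversity_stats(one)$pi, 2 / 3, tolerance = 1e-12)

  # two sequences differing at 2 of 100 sites: pi = 0.02
  aln <- rbind(rep("A", 100), rep("A", 100))
  aln[2, 1:2] <- "G"
  expect_equal(diversity_stats(aln)$pi, 0.02, tolerance = 1e-12)
})

test_that("segregating sites ignore N and missing calls", {
  aln <- rbind(c("A", "C", "T"),
               c("A", "C", "N"),
               c("A", "C", "T"),
               c("G", "C", "A"))
  seg <- segregating_sites(aln)
  expect_identical(seg$S, 2L)
  # a site with a single valid observation is neither segregating nor valid
  single <- matrix(c("A", "N", "-", "-"), 4, 1)
  s2 <- segregating_sites(single)
  expect_identical(s2$S, 0L)
  expect_identical(s2$L_valid, 0L)
  st <- diversity_stats(single)
  expect_true(is.na(st$theta_w) && is.na(st$pi))
})

test_that("Tajima's D has the forced sign and is NA when undefined", {
  # all singletons in a large sample: pi far below theta, D < 0
  counts <- matrix(0L, 200, 4)
  counts[, 1] <- 30L
  counts[1:50, 1] <- 29L
  counts[1:50, 2] <- 1L
  expect_lt(diversity_stats(counts)$tajimas_d, 0)
  # intermediate-frequency variants: pi above theta, D > 0
  counts[1:50, 1] <- 15L
  counts[1:50, 2] <- 15L
  expect_gt(diversity_stats(counts)$tajimas_d, 0)
  # monomorphic: undefined, flagged
  mono <- matrix(rep(c(10L, 0L, 0L, 0L), each = 50), 50, 4)
  expect_identical(diversity_stats(mono)$S, 0L)
  expect_true(is.na(diversity_stats(mono)$tajimas_d))
})

test_that("all statistics match the brute-force oracle on random alignments", {
  withr::with_seed(31, {
    for (rep in 1:15) {
      aln <- random_alignment(5, 120, miss = 0.15, amb = 0.05,
                              n_alleles = sample(2:4, 1))
      st <- diversity_stats(aln)
      oc <- oracle_stats(aln)
      expect_identical(st$S, as.integer(oc$S))
      expect_identical(st$L_valid, as.integer(oc$L_valid))
      expect_equal(st$theta_w, oc$theta_w, tolerance = 1e-12)
      expect_equal(st$pi, oc$pi, tolerance = 1e-12)
      expect_equal(st$tajimas_d, oc$tajimas_d, tolerance = 1e-12)
    }
  })
})

test_that("Hudson Fst matches hand evaluation and the pairwise oracle", {
  # fixed difference at 1 of 100 sites, no within-population variation
  p1 <- matrix("A", 2, 100)
  p2 <- matrix("A", 2, 100)
  p2[, 1] <- "G"
  f <- fst(p1, p2)
  expect_equal(f$hw, 0)
  expect_equal(f$hb, 0.01, tolerance = 1e-12)
  expect_equal(f$fst, 1, tolerance = 1e-12)

  withr::with_seed(32, {
    for (rep in 1:10) {
      a1 <- random_alignment(4, 80, miss = 0.1, amb = 0.05)
      a2 <- random_alignment(5, 80, miss = 0.1, amb = 0.05)
      expect_equal(fst(a1, a2)$fst, oracle_fst(a1, a2), tolerance = 1e-12)
    }
  })
})

test_that("Fst is near zero (small negatives allowed) under panmixia", {
  withr::with_seed(33, {
    vals <- replicate(40, {
      pool <- random_alignment(8, 150, miss = 0, amb = 0, n_alleles = 2)
      fst(pool[1:4, ], pool[5:8, ])$fst
    })
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)) + 0.01)
  expect_true(any(vals < 0))
})

test_that("the polymorphism filter is inclusive at the cutoff", {
  stats <- tibble::tibble(region_id = c("a", "b", "c", "d"),
                          S = c(50L, 49L, 120L, NA))
  kept <- polymorphism_filter(stats, min_S = 50)
  expect_identical(kept$region_id, c("a", "c"))
  expect_identical(nrow(polymorphism_filter(stats[0, ])), 0L)
})

test_that("the Mann-Whitney test matches exact enumeration and handles edge cases", {
  expect_error(mw_test(numeric(0), 1:3), class = "aphidpop_input_error")
  # identical groups: p near 1
  expect_gt(mw_test(c(1, 2, 3, 4), c(1.5, 2.5, 3.5))$p, 0.5)
  # complete separation: U = 0 for the smaller group
  expect_identical(mw_test(c(1, 2, 3), c(4, 5, 6))$u, 0)
  withr::with_seed(34, {
    for (rep in 1:8) {
      x <- runif(sample(3:6, 1))
      y <- runif(sample(3:6, 1))
      expect_equal(mw_test(x, y)$p, oracle_mw_p(x, y), tolerance = 1e-10)
    }
  })
})

test_that("random masking does not systematically shift theta or pi", {
  cfg <- sim_config(n_scaffolds = 1, scaffold_length = 20000, theta = 0.005,
                    n_lines = 10, gene_spacing = 1e9)
  deltas <- vapply(1:6, function(s) {
    ref <- simulate_reference(cfg, seed = 300 + s)
    gen <- simulate_line_genotypes(ref, cfg, seed = 300 + s)
    aln <- hap_alignment(gen, ref, names(ref$sequences)[1])
    full <- diversity_stats(aln)
    withr::with_seed(400 + s, {
      mask <- matrix(runif(length(aln)) < 0.2, nrow(aln))
      aln[mask] <- "-"
    })
    masked <- diversity_stats(aln)
    c(masked$theta_w - full$theta_w, masked$pi - full$pi)
  }, numeric(2))
  for (row in 1:2) {
    se <- sd(deltas[row, ]) / sqrt(ncol(deltas))
    expect_lt(abs(mean(deltas[row, ])), 3 * se + 1e-4)
  }
})

test_that("singleton-skewed spectra drive mean Tajima's D negative", {
  cfg <- sim_config(n_scaffolds = 40, scaffold_length = 8000, theta = 0.005,
                    n_lines = 11, gene_spacing = 1e9, x_fraction = 0)
  ref <- simulate_reference(cfg, seed = 41)
  gen <- simulate_line_genotypes(ref, cfg, seed = 41, sfs_alpha = 2)
  d <- vapply(names(gen$variants), function(sid) {
    v <- gen$variants[[sid]]
    L <- ref$truth$length[ref$truth$scaffold == sid]
    counts <- matrix(0L, L, 4)
    counts[, 1] <- 22L
    if (nrow(v$tbl)) {
      counts[v$tbl$pos, 1] <- 22L - v$tbl$count
      counts[v$tbl$pos, 2] <- v$tbl$count
    }
    diversity_stats(counts)$tajimas_d
  }, 0)
  expect_lt(mean(d), -3 * sd(d) / sqrt(length(d)))
})
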