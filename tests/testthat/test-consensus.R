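test_that("the consensus rule handles its boundary cases exactly", {
  # clear majority above the threshold
  expect_identical(call_consensus_base(c(rep("A", 9), "G"), rep(30, 10)), "A")
  # low-quality reads are removed before the majority rule
  expect_identical(
    call_consensus_base(c(rep("A", 5), rep("G", 5)), c(rep(15, 5), rep(30, 5))),
    "G")
  # exactly 80 percent is not a call: strict inequality
  expect_identical(call_consensus_base(c(rep("A", 8), "G", "G"), rep(30, 10)), "N")
  # balanced heterozygote
  expect_identical(call_consensus_base(c(rep("A", 5), rep("G", 5)), rep(30, 10)), "N")
  # quality exactly at the cutoff is discarded: nothing left, no data
  expect_identical(call_consensus_base(rep("A", 3), rep(20, 3)), NA_character_)
  # no observations at all
  expect_identical(call_consensus_base(character(0), numeric(0)), NA_character_)
  # a modal tie can never clear the threshold
  expect_identical(call_consensus_base(c("A", "A", "G", "G", "T"), rep(30, 5)), "N")
})

test_that("count-based and observation-based consensus agree", {
  withr::with_seed(11, {
    for (rep in 1:50) {
      n <- sample(0:12, 1)
      base <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
      qual <- sample(c(15, 20, 21, 30, 40), n, replace = TRUE)
      keep <- qual > 20
      counts <- matrix(tabulate(match(base[keep], c("A", "C", "G", "T")),
                                nbins = 4), 1, 4)
      expect_identical(call_consensus_base(base, qual),
                       consensus_from_counts(counts))
    }
  })
})

test_that("raising the quality cutoff never increases called bases", {
  withr::with_seed(12, {
    obs <- tibble::tibble(
      scaffold = "s",
      pos = rep(1:200, times = sample(0:6, 200, replace = TRUE))
    )
    obs$ref <- "A"
    obs$base <- sample(c("A", "A", "A", "G"), nrow(obs), replace = TRUE)
    obs$qual <- sample(c(15, 21, 30, 40), nrow(obs), replace = TRUE)
    lens <- c(s = 200L)
    n_with_data <- function(qmin) {
      lc <- build_line_consensus(obs, lens, qmin = qmin)
      sum(lc$calls$s != "-")
    }
    # raising the cutoff can only remove observations, so positions with
    # any data are monotone non-increasing (a dissenting mid-quality read
    # can flip N to a call, so called bases alone are not monotone)
    expect_true(n_with_data(20) >= n_with_data(25))
    expect_true(n_with_data(25) >= n_with_data(35))

    # under the two-tier quality model every retained read has the same
    # quality, and called bases are monotone in the cutoff
    obs2 <- dplyr::mutate(obs, qual = ifelse(.data$qual > 20, 30, 15))
    called2 <- function(qmin) {
      lc <- build_line_consensus(obs2, lens, qmin = qmin)
      sum(lc$calls$s %in% c("A", "C", "G", "T"))
    }
    expect_true(called2(20) >= called2(25))
    expect_true(called2(25) >= called2(35))
  })
})

test_that("consensus building is idempotent and distinguishes N from no data", {
  obs <- tibble::tibble(
    scaffold = "s", pos = c(1L, 1L, 2L, 2L, 3L), ref = "A",
    base = c("A", "G", "A", "A", "C"), qual = c(30, 30, 30, 30, 15))
  lens <- c(s = 4L)
  lc1 <- build_line_consensus(obs, lens, line_id = "L1")
  lc2 <- build_line_consensus(obs, lens, line_id = "L1")
  expect_identical(lc1$calls, lc2$calls)
  # pos 1: balanced -> N; pos 2: unanimous -> A;
  # pos 3: covered but all filtered -> no data; pos 4: uncovered -> no data
  expect_identical(lc1$calls$s, c("N", "A", "-", "-"))
  expect_error(
    build_line_consensus(dplyr::mutate(obs, pos = pos + 10L), lens),
    class = "aphidpop_input_error")
})

test_that("consensus recovers homozygous sites at depth 10 and 1% error", {
  fx_cfg <- tiny_config(n_scaffolds = 2, scaffold_length = c(3000, 3000),
                        theta = 0, error_rate = 0.01, gene_spacing = 1e9)
  ref <- simulate_reference(fx_cfg, seed = 21)
  gen <- simulate_line_genotypes(ref, fx_cfg, seed = 21)
  pair <- simulate_brother_males(gen, ref$truth, line = 1)
  p <- simulate_pileups(pair, ref, male = 1, depth = 10, config = fx_cfg,
                        seed = 21)
  lc <- build_line_consensus(pileup_observations(p),
                             setNames(ref$truth$length, ref$truth$scaffold),
                             line_id = "L1")
  correct <- 0L; called <- 0L
  for (sid in names(lc$calls)) {
    truth_chars <- strsplit(ref$sequences[[sid]], "")[[1]]
    v <- lc$calls[[sid]]
    idx <- v %in% c("A", "C", "G", "T")
    called <- called + sum(idx)
    correct <- correct + sum(v[idx] == truth_chars[idx])
  }
  expect_gt(correct / called, 0.999)
})

test_that("consensus sequences round-trip through FASTA", {
  lc <- fake_consensus("L7", list(sc1 = c("A", "N", "-", "T"),
                                  sc2 = c("G", "G")))
  path <- withr::local_tempfile(fileext = ".fa")
  write_consensus_fasta(lc, path)
  back <- read_consensus_fasta(path)
  expect_identical(back$line_id, "L7")
  expect_identical(back$calls, lc$calls)
})
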