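test_that("theta = 0 leaves every line identical to the reference", {
  cfg <- tiny_config(theta = 0)
  ref <- simulate_reference(cfg, seed = 1)
  gen <- simulate_line_genotypes(ref, cfg, seed = 1)
  expect_identical(nrow(variant_table(gen)), 0L)
  aln <- hap_alignment(gen, ref, names(ref$sequences)[1])
  ref_chars <- strsplit(ref$sequences[[1]], "")[[1]]
  expect_true(all(aln == rep(ref_chars, each = nrow(aln))))
})

test_that("a single line yields two haplotypes and S equals its heterozygous sites", {
  cfg <- tiny_config(n_lines = 1, n_scaffolds = 2)
  ref <- simulate_reference(cfg, seed = 2)
  gen <- simulate_line_genotypes(ref, cfg, seed = 2)
  expect_identical(gen$n_hap, 2L)
  v <- gen$variants[[1]]
  # with 2 haplotypes every site has derived count 1: always heterozygous
  expect_true(all(v$tbl$count == 1))
  aln <- hap_alignment(gen, ref, names(ref$sequences)[1])
  het <- sum(aln[1, ] != aln[2, ])
  expect_identical(het, nrow(v$tbl))
})

test_that("realized pairwise diversity matches theta within Monte-Carlo error", {
  cfg <- sim_config(n_scaffolds = 1, scaffold_length = 30000, theta = 0.005,
                    n_lines = 21, gene_spacing = 1e9)
  pis <- vapply(1:10, function(s) {
    ref <- simulate_reference(cfg, seed = s)
    gen <- simulate_line_genotypes(ref, cfg, seed = s)
    v <- gen$variants[[1]]
    i <- v$tbl$count
    m <- gen$n_hap
    sum(2 * i * (m - i) / (m * (m - 1))) / ref$truth$length[1]
  }, 0)
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - 0.005), 3 * se)
})

test_that("derived-allele counts follow the neutral 1/i spectrum", {
  cfg <- sim_config(n_scaffolds = 1, scaffold_length = 50000, theta = 0.005,
                    n_lines = 11, gene_spacing = 1e9)
  p_values <- vapply(1:5, function(s) {
    ref <- simulate_reference(cfg, seed = 100 + s)
    gen <- simulate_line_genotypes(ref, cfg, seed = 100 + s)
    counts <- variant_table(gen)$count
    m <- gen$n_hap
    obs <- tabulate(counts, nbins = m - 1)
    expected_p <- (1 / seq_len(m - 1)) / sum(1 / seq_len(m - 1))
    suppressWarnings(stats::chisq.test(obs, p = expected_p))$p.value
  }, 0)
  expect_gt(median(p_values), 0.05)
  expect_true(all(p_values > 0.001))
})

test_that("impossible site densities are refused", {
  cfg <- tiny_config(theta = 0.05, n_lines = 21)
  ref <- simulate_reference(tiny_config(), seed = 1)
  expect_error(simulate_line_genotypes(ref, cfg, seed = 1),
               class = "aphidpop_config_error")
})

test_that("mutation-class labels agree with direct codon translation", {
  cfg <- tiny_config(n_scaffolds = 3, gene_spacing = 3000)
  ref <- simulate_reference(cfg, seed = 6)
  spectra <- tibble::tibble(class = c("synonymous", "nonsynonymous"),
                            alpha = c(1, 1))
  gen <- simulate_line_genotypes(ref, cfg, seed = 6, class_spectra = spectra)
  vt <- variant_table(gen)
  coding <- vt[vt$class != "noncoding", ]
  skip_if(nrow(coding) == 0, "no coding variants drawn in this fixture")
  cds <- ref$annotation[ref$annotation$type == "CDS", ]
  for (k in seq_len(min(nrow(coding), 40))) {
    row <- coding[k, ]
    seg_all <- cds[cds$seqid == row$scaffold &
                     cds$start <= row$pos & cds$end >= row$pos, ]
    expect_identical(nrow(seg_all), 1L)
    gid <- seg_all$gene_id[1]
    seg <- cds[cds$gene_id == gid, ]
    strand <- seg$strand[1]
    seg <- seg[order(seg$start, decreasing = (strand == "-")), ]
    chars <- strsplit(ref$sequences[[row$scaffold]], "")[[1]]
    gpos <- unlist(lapply(seq_len(nrow(seg)), function(j) {
      p <- seg$start[j]:seg$end[j]
      if (strand == "-") rev(p) else p
    }))
    ci <- which(gpos == row$pos)
    codon_pos <- gpos[((ci - 1) %/% 3) * 3 + 1:3]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    codon <- chars[codon_pos]
    alt_codon <- codon
    alt_codon[which(codon_pos == row$pos)] <- row$alt
    if (strand == "-") {
      codon <- unname(comp[codon]); alt_codon <- unname(comp[alt_codon])
    }
    aa1 <- unname(Biostrings::GENETIC_CODE[paste(codon, collapse = "")])
    aa2 <- unname(Biostrings::GENETIC_CODE[paste(alt_codon, collapse = "")])
    expect_identical(row$class,
                     if (identical(aa1, aa2)) "synonymous" else "nonsynonymous")
  }
})
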