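test_that("reference simulation is deterministic for a fixed seed", {
  cfg <- tiny_config()
  r1 <- simulate_reference(cfg, seed = 5)
  r2 <- simulate_reference(cfg, seed = 5)
  expect_identical(r1$sequences, r2$sequences)
  expect_identical(r1$truth, r2$truth)
  expect_identical(r1$annotation, r2$annotation)
  r3 <- simulate_reference(cfg, seed = 6)
  expect_false(identical(r1$sequences, r3$sequences))
})

test_that("x_fraction boundaries and chimera counts are honoured", {
  none <- simulate_reference(tiny_config(x_fraction = 0, n_scaffolds = 20), seed = 1)
  expect_false(any(none$truth$label == "X"))

  all_x <- simulate_reference(tiny_config(x_fraction = 1, n_scaffolds = 10), seed = 1)
  expect_true(all(all_x$truth$label == "X"))

  chim <- simulate_reference(
    tiny_config(n_scaffolds = 100, chimera_fraction = 0.05,
                scaffold_length = c(2000, 3000), gene_spacing = 1e9),
    seed = 2)
  expect_identical(sum(chim$truth$label == "chimera"), 5L)
  bp <- chim$truth$breakpoint[chim$truth$label == "chimera"]
  expect_true(all(!is.na(bp)))
  expect_true(all(bp > 0 & bp < chim$truth$length[chim$truth$label == "chimera"]))
  segs <- truth_segments(chim$truth)
  expect_identical(sort(unique(segs$scaffold)), sort(chim$truth$scaffold))
  # chimeras contribute one X and one A segment
  chim_segs <- segs[segs$scaffold %in% chim$truth$scaffold[chim$truth$label == "chimera"], ]
  expect_true(all(table(chim_segs$scaffold) == 2))
})

test_that("X scaffold count is binomial around n * x_fraction", {
  counts <- vapply(1:5, function(s) {
    r <- simulate_reference(
      sim_config(n_scaffolds = 300, scaffold_length = 1000, x_fraction = 0.12,
                 gene_spacing = 1e9), seed = s)
    sum(r$truth$label == "X")
  }, 0)
  n_tot <- 5 * 300
  p_hat <- sum(counts) / n_tot
  se <- sqrt(0.12 * 0.88 / n_tot)
  expect_lt(abs(p_hat - 0.12), 4 * se)
})

test_that("gene models are well-formed: in-frame, stop-free CDS inside scaffolds", {
  ref <- simulate_reference(tiny_config(n_scaffolds = 4), seed = 3)
  ann <- ref$annotation
  expect_true(all(c("gene", "mRNA", "exon", "CDS", "five_prime_UTR",
                    "three_prime_UTR") %in% ann$type))
  lens <- setNames(ref$truth$length, ref$truth$scaffold)
  expect_true(all(ann$start >= 1 & ann$end <= lens[ann$seqid]))
  cds <- ann[ann$type == "CDS", ]
  for (gid in unique(cds$gene_id)) {
    seg <- cds[cds$gene_id == gid, ]
    strand <- seg$strand[1]
    total <- sum(seg$end - seg$start + 1)
    expect_identical(total %% 3, 0)
    seg <- seg[order(seg$start, decreasing = (strand == "-")), ]
    chars <- strsplit(ref$sequences[[seg$seqid[1]]], "")[[1]]
    coding <- unlist(lapply(seq_len(nrow(seg)), function(k) {
      piece <- chars[seg$start[k]:seg$end[k]]
      if (strand == "-") rev(unname(c(A = "T", C = "G", G = "C", T = "A")[piece]))
      else piece
    }))
    codons <- apply(matrix(coding, nrow = 3), 2, paste, collapse = "")
    aa <- unname(Biostrings::GENETIC_CODE[codons])
    expect_false(any(aa == "*"))
  }
})

test_that("gff3 files round-trip through write and read", {
  ref <- simulate_reference(tiny_config(n_scaffolds = 3), seed = 4)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ref$annotation, path,
             setNames(ref$truth$length, ref$truth$scaffold))
  back <- read_gff3(path)
  for (col in c("seqid", "type", "start", "end", "strand", "gene_id")) {
    expect_identical(back[[col]], ref$annotation[[col]])
  }
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_scaffolds = 0), class = "aphidpop_config_error")
  expect_error(sim_config(scaffold_length = 0), class = "aphidpop_config_error")
  expect_error(sim_config(x_fraction = 1.5), class = "aphidpop_config_error")
  expect_error(sim_config(qual_low = 25), class = "aphidpop_config_error")
})
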