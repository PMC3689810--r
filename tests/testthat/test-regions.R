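hand_annotation <- function(start, end, strand = "+", exons = NULL,
                            scaffold = "sc", gid = "g1") {
  exons <- exons %||% list(c(start, end))
  rows <- list(
    tibble::tibble(seqid = scaffold, type = "gene", start = start, end = end,
                   strand = strand, phase = NA_integer_, gene_id = gid,
                   feature_id = gid, parent = NA_character_)
  )
  for (k in seq_along(exons)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      seqid = scaffold, type = "exon", start = exons[[k]][1],
      end = exons[[k]][2], strand = strand, phase = NA_integer_,
      gene_id = gid, feature_id = paste0(gid, ".e", k), parent = gid)
    rows[[length(rows) + 1]] <- tibble::tibble(
      seqid = scaffold, type = "CDS", start = exons[[k]][1],
      end = exons[[k]][2], strand = strand, phase = 0L,
      gene_id = gid, feature_id = paste0(gid, ".cds"), parent = gid)
  }
  dplyr::bind_rows(rows)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("flank coordinates are strand-aware and clipped at scaffold ends", {
  ann <- hand_annotation(20000L, 30000L, "+")
  regs <- extract_regions(ann, c(sc = 50000L))
  up <- regs[regs$kind == "upstream", ]
  expect_identical(c(up$start, up$end), c(10000L, 19999L))
  dn <- regs[regs$kind == "downstream", ]
  expect_identical(c(dn$start, dn$end), c(30001L, 40000L))
  gf <- regs[regs$kind == "gene_flank", ]
  expect_identical(c(gf$start, gf$end), c(15000L, 35000L))

  minus <- extract_regions(hand_annotation(20000L, 30000L, "-"), c(sc = 50000L))
  expect_identical(minus[minus$kind == "upstream", ]$start, 30001L)
  expect_identical(minus[minus$kind == "downstream", ]$end, 19999L)

  near_edge <- extract_regions(hand_annotation(4000L, 6000L, "+"), c(sc = 50000L))
  up2 <- near_edge[near_edge$kind == "upstream", ]
  expect_identical(c(up2$start, up2$end), c(1L, 3999L))
})

test_that("single-exon genes produce no intron regions", {
  regs <- extract_regions(hand_annotation(1000L, 1299L), c(sc = 5000L))
  expect_identical(sum(regs$kind == "intron"), 0L)
  two <- extract_regions(
    hand_annotation(1000L, 1599L, exons = list(c(1000L, 1299L), c(1500L, 1599L))),
    c(sc = 5000L))
  intr <- two[two$kind == "intron", ]
  expect_identical(c(intr$start, intr$end), c(1300L, 1499L))
})

test_that("coding-orientation extraction reverse-complements minus-strand genes", {
  aln <- rbind(c("A", "C", "G", "T", "T", "A"))
  parts <- tibble::tibble(gene_id = "g", kind = "cds", scaffold = "sc",
                          strand = "-", part = 1L, start = 1L, end = 6L)
  cod <- region_alignment(aln, parts, orient = "coding")
  expect_identical(cod[1, ], c("T", "A", "A", "C", "G", "T"))
})

test_that("synonymous and nonsynonymous site classes follow the genetic code", {
  # third-position GGA/GGG: both glycine
  aln <- rbind(c("G", "G", "A"), c("G", "G", "G"), c("G", "G", "A"))
  cls <- classify_syn_nonsyn(aln)
  expect_identical(cls$class, c("invariant", "invariant", "synonymous"))
  # second-position GGA/GAA: glycine vs glutamate
  aln2 <- rbind(c("G", "G", "A"), c("G", "A", "A"))
  expect_identical(classify_syn_nonsyn(aln2)$class[2], "nonsynonymous")
  # two variable positions in one codon: excluded
  aln3 <- rbind(c("G", "G", "A"), c("A", "G", "G"))
  expect_true(all(classify_syn_nonsyn(aln3)$class == "ambiguous"))
  # missing background position: excluded
  aln4 <- rbind(c("-", "G", "A"), c("-", "G", "G"))
  expect_identical(classify_syn_nonsyn(aln4)$class[3], "ambiguous")
  # fixed internal stop flags the gene
  aln5 <- rbind(c("T", "A", "A", "G", "G", "A"), c("T", "A", "A", "G", "G", "G"))
  expect_true(attr(classify_syn_nonsyn(aln5), "stop_codon"))
  expect_error(classify_syn_nonsyn(aln5[, 1:4]), class = "aphidpop_input_error")
})
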