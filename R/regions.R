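#' Derive analysis regions from a gene annotation
#'
#' For every annotated gene, emits the eight region kinds analysed
#' throughout the package: the whole gene (coding, UTRs and introns), the
#' gene plus 5 kb of flank on each side, the CDS, 5' and 3' UTRs, introns
#' (the gene span minus its exons), and the 10-kb upstream and downstream
#' intergenic regions.  Flanks are strand-aware (upstream of a `-` strand
#' gene lies to its right) and clipped at scaffold ends, but deliberately
#' not clipped at neighbouring genes, so flank regions may overlap other
#' genes.  A region may consist of several parts (CDS exons, introns); parts
#' carry a `part` index in coding order.
#'
#' @param annotation GFF3-style tibble (see [simulate_reference()] or
#'   [read_gff3()]), 1-based inclusive coordinates.
#' @param scaffold_lengths Named vector of scaffold lengths used for
#'   clipping.
#' @param flank_gene Flank width for the gene-plus-flanks region (bp).
#' @param flank_igr Width of the upstream/downstream intergenic regions (bp).
#' @return Tibble: gene_id, kind, scaffold, strand, part, start, end.
#' @export
extract_regions <- function(annotation, scaffold_lengths,
                            flank_gene = 5000, flank_igr = 10000) {
  genes <- annotation[annotation$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) {
    return(tibble(gene_id = character(), kind = character(),
                  scaffold = character(), strand = character(),
                  part = integer(), start = integer(), end = integer()))
  }
  out <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    L <- unname(scaffold_lengths[[g$seqid]])
    if (is.null(L) || is.na(L)) stop_input(sprintf("no length for scaffold '%s'", g$seqid))
    feat <- annotation[annotation$gene_id == g$gene_id, , drop = FALSE]
    plus <- g$strand == "+"

    mk <- function(kind, start, end, part = NULL) {
      start <- pmax(1L, as.integer(start))
      end <- pmin(as.integer(L), as.integer(end))
      keep <- start <= end
      if (!any(keep)) return(NULL)
      tibble(gene_id = g$gene_id, kind = kind, scaffold = g$seqid,
             strand = g$strand,
             part = (part %||% seq_len(sum(keep)))[keep],
             start = start[keep], end = end[keep])
    }

    cds <- feat[feat$type == "CDS", , drop = FALSE]
    cds <- cds[order(cds$start, decreasing = !plus), , drop = FALSE]
    exons <- feat[feat$type == "exon", , drop = FALSE]
    exons <- exons[order(exons$start), , drop = FALSE]
    utr5 <- feat[feat$type == "five_prime_UTR", , drop = FALSE]
    utr3 <- feat[feat$type == "three_prime_UTR", , drop = FALSE]

    # introns: gene span minus exons (genomic order)
    introns <- NULL
    if (nrow(exons) > 1) {
      istart <- exons$end[-nrow(exons)] + 1L
      iend <- exons$start[-1] - 1L
      keep <- istart <= iend
      if (any(keep)) introns <- list(start = istart[keep], end = iend[keep])
    }

    up_start <- if (plus) g$start - flank_igr else g$end + 1L
    up_end <- if (plus) g$start - 1L else g$end + flank_igr
    dn_start <- if (plus) g$end + 1L else g$start - flank_igr
    dn_end <- if (plus) g$end + flank_igr else g$start - 1L

    dplyr::bind_rows(
      mk("gene", g$start, g$end, 1L),
      mk("gene_flank", g$start - flank_gene, g$end + flank_gene, 1L),
      if (nrow(cds)) mk("cds", cds$start, cds$end, seq_len(nrow(cds))),
      if (nrow(utr5)) mk("utr5", utr5$start, utr5$end, seq_len(nrow(utr5))),
      if (nrow(utr3)) mk("utr3", utr3$start, utr3$end, seq_len(nrow(utr3))),
      if (!is.null(introns)) mk("intron", introns$start, introns$end,
                                seq_along(introns$start)),
      mk("upstream", up_start, up_end, 1L),
      mk("downstream", dn_start, dn_end, 1L)
    )
  })
  dplyr::bind_rows(out)
}

#' Extract a region's alignment columns from a scaffold alignment
#'
#' Concatenates the region's parts.  For `orient = "coding"` the parts are
#' ordered 5' to 3' and reverse-complemented on `-` strand genes, which is
#' required before codon-level classification; diversity statistics are
#' orientation-invariant.
#'
#' @param scaffold_aln Character matrix (lines x scaffold length).
#' @param region_parts Rows of [extract_regions()] for one region.
#' @param orient `"genomic"` or `"coding"`.
#' @return Character matrix of the region's columns.
#' @export
region_alignment <- function(scaffold_aln, region_parts, orient = c("genomic", "coding")) {
  orient <- match.arg(orient)
  strand <- region_parts$strand[1]
  parts <- region_parts
  if (orient == "coding" && strand == "-") {
    parts <- parts[order(parts$start, decreasing = TRUE), , drop = FALSE]
  } else {
    parts <- parts[order(parts$start), , drop = FALSE]
  }
  cols <- unlist(purrr::map(seq_len(nrow(parts)), function(k) {
    idx <- parts$start[k]:parts$end[k]
    if (orient == "coding" && strand == "-") rev(idx) else idx
  }), use.names = FALSE)
  out <- scaffold_aln[, cols, drop = FALSE]
  if (orient == "coding" && strand == "-") {
    out[] <- comp_base(out)
  }
  out
}

#' Classify variable CDS sites as synonymous or nonsynonymous
#'
#' Operates on a coding-orientation CDS alignment.  A codon position is
#' variable when at least two distinct valid (non-N, non-missing) alleles
#' are observed there.  For codons variable at exactly one position, every
#' observed allele is substituted into the codon's majority-base background
#' (low-coverage consensus data rarely yield complete per-line codons, so
#' the two invariant positions are taken as their modal observed base): the
#' site is synonymous if all resulting codons encode the same amino acid,
#' otherwise nonsynonymous.  Codons variable at more than one position, or
#' whose background contains a position with no valid observation, are
#' `ambiguous` and excluded from site-class statistics.  A fixed internal
#' stop codon flags the gene (attribute `stop_codon`).
#'
#' @param cds_aln Character matrix in coding orientation; its width must be
#'   a multiple of 3.
#' @return Tibble: site (1-based position in the CDS), codon, class in
#'   `synonymous`/`nonsynonymous`/`ambiguous`/`invariant`; attribute
#'   `stop_codon` is TRUE if a fixed internal stop was seen.
#' @export
classify_syn_nonsyn <- function(cds_aln) {
  w <- ncol(cds_aln)
  if (w %% 3 != 0) stop_input("CDS alignment length is not a multiple of 3")
  n_codons <- w %/% 3
  counts <- allele_counts(cds_aln)
  n_valid <- rowSums(counts)
  n_alleles <- rowSums(counts > 0)
  background <- rep(NA_character_, w)
  has_data <- n_valid > 0
  background[has_data] <- BASES[max.col(counts[has_data, , drop = FALSE],
                                        ties.method = "first")]
  class <- rep("invariant", w)
  stop_seen <- FALSE
  for (cd in seq_len(n_codons)) {
    idx <- (cd - 1L) * 3L + 1:3
    bg <- background[idx]
    if (all(!is.na(bg))) {
      aa_bg <- translate_codons(paste(bg, collapse = ""))
      if (cd < n_codons && aa_bg == "*") stop_seen <- TRUE
    }
    var_pos <- which(n_alleles[idx] >= 2)
    if (length(var_pos) == 0) next
    if (length(var_pos) > 1 || any(is.na(bg))) {
      class[idx] <- "ambiguous"
      next
    }
    site <- idx[var_pos]
    alleles <- BASES[counts[site, ] > 0]
    aa <- vapply(alleles, function(b) {
      codon <- bg
      codon[var_pos] <- b
      translate_codons(paste(codon, collapse = ""))
    }, "")
    class[site] <- if (length(unique(aa)) == 1) "synonymous" else "nonsynonymous"
  }
  out <- tibble(site = seq_len(w),
                codon = rep(seq_len(n_codons), each = 3L),
                class = class)
  attr(out, "stop_codon") <- stop_seen
  out
}

#' Write a GFF3 annotation file
#'
#' @param annotation Annotation tibble (see [simulate_reference()]).
#' @param path Output file.
#' @param scaffold_lengths Optional named lengths for sequence-region
#'   pragmas.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path, scaffold_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(scaffold_lengths)) {
    writeLines(sprintf("##sequence-region %s 1 %d", names(scaffold_lengths),
                       scaffold_lengths), con)
  }
  attrs <- ifelse(
    is.na(annotation$parent),
    sprintf("ID=%s;gene_id=%s", annotation$feature_id, annotation$gene_id),
    sprintf("ID=%s;Parent=%s;gene_id=%s", annotation$feature_id,
            annotation$parent, annotation$gene_id)
  )
  lines <- sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                   annotation$seqid, annotation$type, annotation$start,
                   annotation$end, annotation$strand,
                   ifelse(is.na(annotation$phase), ".", annotation$phase),
                   attrs)
  writeLines(lines, con)
  invisible(path)
}

#' Read a GFF3 file into the package's annotation tibble
#'
#' @param path GFF3 file.
#' @return Annotation tibble with columns seqid, type, start, end, strand,
#'   phase, gene_id, feature_id, parent.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- stringr::str_split_fixed(lines, "\t", 9)
  get_attr <- function(attr, key) {
    m <- stringr::str_match(attr, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    m
  }
  tibble(
    seqid = f[, 1], type = f[, 3],
    start = as.integer(f[, 4]), end = as.integer(f[, 5]),
    strand = f[, 7],
    phase = suppressWarnings(as.integer(f[, 8])),
    gene_id = get_attr(f[, 9], "gene_id"),
    feature_id = get_attr(f[, 9], "ID"),
    parent = get_attr(f[, 9], "Parent")
  )
}
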