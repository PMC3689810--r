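#' Simulate a reference assembly with hidden X/autosome identities
#'
#' Draws scaffold lengths and labels, builds random reference sequences with
#' annotated protein-coding genes (5' UTR, CDS exons, introns, 3' UTR), and
#' records a truth table giving each scaffold's hidden chromosome class.
#' Chimeric scaffolds join one X-linked and one autosomal segment at a single
#' uniformly placed breakpoint, emulating misassembled scaffolds.
#'
#' Coding sequence is built from sense codons only (no in-frame stops) and
#' every CDS length is a multiple of three, so downstream codon-level
#' classification is always in frame.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to the seed stored in `config` or 1.
#' @return A `sim_reference` list with elements `sequences` (named character
#'   vector, one string per scaffold), `truth` (tibble: scaffold, length,
#'   label, breakpoint and per-segment labels for chimeras), `annotation`
#'   (GFF3-style tibble) and `config`.
#' @export
simulate_reference <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed %||% 1L
  local_seed(derive_seed(seed, 1L), {
    n <- config$n_scaffolds
    lens <- as.integer(round(runif(n, config$scaffold_length[1], config$scaffold_length[2])))
    ids <- sprintf("scaffold_%04d", seq_len(n))

    n_chim <- as.integer(round(config$chimera_fraction * n))
    chim_idx <- if (n_chim > 0) sample.int(n, n_chim) else integer(0)
    label <- ifelse(runif(n) < config$x_fraction, "X", "A")
    label[chim_idx] <- "chimera"
    breakpoint <- rep(NA_integer_, n)
    left_label <- right_label <- rep(NA_character_, n)
    if (n_chim > 0) {
      breakpoint[chim_idx] <- as.integer(round(runif(n_chim, 0.2, 0.8) * lens[chim_idx]))
      x_left <- runif(n_chim) < 0.5
      left_label[chim_idx] <- ifelse(x_left, "X", "A")
      right_label[chim_idx] <- ifelse(x_left, "A", "X")
    }
    truth <- tibble(
      scaffold = ids, length = lens, label = label,
      breakpoint = breakpoint, left_label = left_label, right_label = right_label
    )

    seqs <- character(n)
    ann <- vector("list", n)
    for (i in seq_len(n)) {
      chars <- random_dna(lens[i])
      genes <- .place_genes(ids[i], lens[i], config$gene_spacing)
      if (nrow(genes$features) > 0) {
        chars <- .fill_coding_sequence(chars, genes$features)
      }
      seqs[i] <- paste(chars, collapse = "")
      ann[[i]] <- genes$features
    }
    names(seqs) <- ids
    annotation <- dplyr::bind_rows(ann)

    structure(
      list(sequences = seqs, truth = truth, annotation = annotation, config = config),
      class = "sim_reference"
    )
  })
}

# Lay out non-overlapping gene models along one scaffold.  Returns GFF3-style
# rows (gene/mRNA/exon/CDS/five_prime_UTR/three_prime_UTR) in 1-based
# inclusive coordinates.  Exon 1 holds the 5' UTR plus the first CDS piece,
# the last exon the final CDS piece plus the 3' UTR (mirrored on '-' strand).
.place_genes <- function(scaffold, len, spacing) {
  rows <- list()
  cursor <- as.integer(runif(1, spacing * 0.2, spacing * 0.8))
  g <- 0L
  while (TRUE) {
    u5 <- as.integer(runif(1, 100, 400))
    u3 <- as.integer(runif(1, 100, 400))
    n_ex <- sample(2:5, 1)
    cds_len <- 3L * as.integer(runif(n_ex, 50, 150))
    intron_len <- as.integer(runif(n_ex - 1, 300, 1500))
    span <- u5 + u3 + sum(cds_len) + sum(intron_len)
    if (cursor + span - 1 > len) break
    g <- g + 1L
    strand <- sample(c("+", "-"), 1)
    gid <- sprintf("%s_g%03d", scaffold, g)
    gstart <- cursor
    gend <- cursor + span - 1L

    # genomic layout left to right: [utrL][cds1][intron]...[cdsN][utrR]
    utrL <- if (strand == "+") u5 else u3
    utrR <- if (strand == "+") u3 else u5
    cds_genomic <- if (strand == "+") cds_len else rev(cds_len)
    seg_start <- integer(n_ex)
    seg_end <- integer(n_ex)
    p <- gstart + utrL
    for (k in seq_len(n_ex)) {
      seg_start[k] <- p
      seg_end[k] <- p + cds_genomic[k] - 1L
      p <- seg_end[k] + 1L + if (k < n_ex) intron_len[k] else 0L
    }
    # exons: CDS pieces, with terminal UTRs attached to first/last exon
    ex_start <- seg_start
    ex_end <- seg_end
    ex_start[1] <- gstart
    ex_end[n_ex] <- gend

    # CDS phase in coding order
    ord <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    phase <- integer(n_ex)
    cum <- 0L
    for (k in ord) {
      phase[k] <- (3L - cum %% 3L) %% 3L
      cum <- cum + (seg_end[k] - seg_start[k] + 1L)
    }

    rows[[length(rows) + 1L]] <- dplyr::bind_rows(
      tibble(seqid = scaffold, type = "gene", start = gstart, end = gend,
             strand = strand, phase = NA_integer_, gene_id = gid,
             feature_id = gid, parent = NA_character_),
      tibble(seqid = scaffold, type = "mRNA", start = gstart, end = gend,
             strand = strand, phase = NA_integer_, gene_id = gid,
             feature_id = paste0(gid, ".t1"), parent = gid),
      tibble(seqid = scaffold, type = "exon", start = ex_start, end = ex_end,
             strand = strand, phase = NA_integer_, gene_id = gid,
             feature_id = sprintf("%s.e%d", gid, seq_len(n_ex)),
             parent = paste0(gid, ".t1")),
      tibble(seqid = scaffold, type = "CDS", start = seg_start, end = seg_end,
             strand = strand, phase = phase, gene_id = gid,
             feature_id = paste0(gid, ".cds"), parent = paste0(gid, ".t1")),
      tibble(seqid = scaffold,
             type = if (strand == "+") "five_prime_UTR" else "three_prime_UTR",
             start = gstart, end = gstart + utrL - 1L, strand = strand,
             phase = NA_integer_, gene_id = gid,
             feature_id = paste0(gid, ".utrL"), parent = paste0(gid, ".t1")),
      tibble(seqid = scaffold,
             type = if (strand == "+") "three_prime_UTR" else "five_prime_UTR",
             start = gend - utrR + 1L, end = gend, strand = strand,
             phase = NA_integer_, gene_id = gid,
             feature_id = paste0(gid, ".utrR"), parent = paste0(gid, ".t1"))
    )
    cursor <- gend + 1L + as.integer(runif(1, spacing * 0.3, spacing * 1.2))
  }
  features <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(seqid = character(), type = character(), start = integer(),
           end = integer(), strand = character(), phase = integer(),
           gene_id = character(), feature_id = character(), parent = character())
  list(features = features)
}

# Overwrite CDS intervals with stop-free codons (in coding orientation).
.fill_coding_sequence <- function(chars, features) {
  cds <- features[features$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) return(chars)
  for (gid in unique(cds$gene_id)) {
    seg <- cds[cds$gene_id == gid, , drop = FALSE]
    strand <- seg$strand[1]
    seg <- seg[order(seg$start, decreasing = (strand == "-")), , drop = FALSE]
    total <- sum(seg$end - seg$start + 1L)
    coding <- sample(SENSE_CODON_CHARS, total %/% 3L, replace = TRUE)
    coding <- unlist(strsplit(coding, "", fixed = TRUE), use.names = FALSE)
    off <- 0L
    for (k in seq_len(nrow(seg))) {
      w <- seg$end[k] - seg$start[k] + 1L
      piece <- coding[(off + 1L):(off + w)]
      if (strand == "-") piece <- revcomp_chars(piece)
      chars[seg$start[k]:seg$end[k]] <- piece
      off <- off + w
    }
  }
  chars
}

#' @export
print.sim_reference <- function(x, ...) {
  cat(sprintf("<sim_reference> %d scaffolds, %.3g Mb total, %d genes\n",
              length(x$sequences), sum(x$truth$length) / 1e6,
              sum(x$annotation$type == "gene")))
  invisible(x)
}

#' Scaffold segments by chromosome class
#'
#' Expands the truth table into per-segment rows: pure scaffolds yield one
#' segment covering their whole length, chimeras yield one segment per side
#' of the breakpoint.
#'
#' @param truth Truth tibble from [simulate_reference()].
#' @return Tibble with columns scaffold, start, end, seg_label.
#' @export
truth_segments <- function(truth) {
  purrr::pmap_dfr(truth, function(scaffold, length, label, breakpoint,
                                  left_label, right_label, ...) {
    if (identical(label, "chimera")) {
      tibble(scaffold = scaffold,
             start = c(1L, breakpoint + 1L),
             end = c(breakpoint, length),
             seg_label = c(left_label, right_label))
    } else {
      tibble(scaffold = scaffold, start = 1L, end = length, seg_label = label)
    }
  })
}
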