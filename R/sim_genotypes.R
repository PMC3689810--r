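#' Simulate diploid line genotypes under the neutral site-frequency spectrum
#'
#' Places segregating sites on each scaffold under the infinite-sites model.
#' Site positions are sampled without replacement (the infinite-sites
#' assumption: one mutation per site).  Each site's derived-allele count
#' `i` among the `2 * n_lines` haplotypes is drawn proportional to
#' `i^(-sfs_alpha)` over `i = 1 .. 2n - 1`; `sfs_alpha = 1` is the neutral
#' equilibrium spectrum, larger values skew the spectrum toward singletons
#' (a population-expansion-like excess of rare variants).  The per-bp density
#' of segregating sites is `theta * a1(2n)` (with `a1` the Watterson
#' harmonic sum), which makes the expected pairwise diversity per bp equal
#' to `theta` under the neutral spectrum.
#'
#' Line `j` is the diploid formed by haplotypes `2j - 1` and `2j`.
#'
#' @param reference A [simulate_reference()] result.
#' @param config The [sim_config()] used (supplies `theta` and `n_lines`).
#' @param seed Integer seed.
#' @param sfs_alpha Spectrum shape; derived counts are drawn with probability
#'   proportional to `i^(-sfs_alpha)`.
#' @param class_spectra Optional tibble with columns `class`
#'   (one of `"noncoding"`, `"synonymous"`, `"nonsynonymous"`) and `alpha`,
#'   overriding `sfs_alpha` per mutation class, and optionally `rel_rate`
#'   (a relative site-retention probability, emulating purifying constraint
#'   by thinning a class's segregating sites).  Site classes are determined
#'   from the annotated reading frame and the drawn alternate base, so a
#'   skew can be placed specifically on nonsynonymous mutations.
#' @return A `line_genotypes` object: per-scaffold variant tables
#'   (position, ref, alt, mutation class, derived count) with a logical
#'   haplotype-by-site carrier matrix.
#' @export
simulate_line_genotypes <- function(reference, config, seed = NULL,
                                    sfs_alpha = 1, class_spectra = NULL) {
  stopifnot(inherits(reference, "sim_reference"))
  seed <- seed %||% config$seed %||% 1L
  n_hap <- 2L * config$n_lines
  if (config$theta > 0 && n_hap < 2) {
    stop_config("at least one line is required to segregate variation")
  }
  a1 <- sum(1 / seq_len(max(n_hap - 1L, 1L)))
  density <- config$theta * a1
  if (density > 0.1) {
    stop_config(sprintf(
      "theta = %g implies %.3g segregating sites per bp; the infinite-sites placement cannot support this density",
      config$theta, density))
  }
  cds_maps <- if (!is.null(class_spectra)) .build_cds_maps(reference) else NULL

  local_seed(derive_seed(seed, 2L), {
    variants <- purrr::imap(reference$sequences, function(seq, sid) {
      L <- nchar(seq)
      n_sites <- rpois(1, density * L)
      if (n_sites == 0 || config$theta == 0) {
        return(list(
          tbl = tibble(pos = integer(), ref = character(), alt = character(),
                       class = character(), count = integer()),
          H = matrix(FALSE, 0, n_hap)
        ))
      }
      n_sites <- min(n_sites, L)
      pos <- sort(sample.int(L, n_sites))
      ref <- strsplit(substr(seq, 1, L), "")[[1]][pos]
      alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), "",
                    USE.NAMES = FALSE)
      cls <- .classify_mutations(sid, pos, alt, cds_maps)
      alpha <- rep(sfs_alpha, n_sites)
      if (!is.null(class_spectra)) {
        m <- match(cls, class_spectra$class)
        alpha[!is.na(m)] <- class_spectra$alpha[m[!is.na(m)]]
        if ("rel_rate" %in% names(class_spectra)) {
          rate <- rep(1, n_sites)
          rate[!is.na(m)] <- class_spectra$rel_rate[m[!is.na(m)]]
          keep <- runif(n_sites) <= rate
          pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]
          cls <- cls[keep]; alpha <- alpha[keep]
          n_sites <- sum(keep)
          if (n_sites == 0) {
            return(list(
              tbl = tibble(pos = integer(), ref = character(),
                           alt = character(), class = character(),
                           count = integer()),
              H = matrix(FALSE, 0, n_hap)
            ))
          }
        }
      }
      count <- vapply(alpha, function(a) {
        i <- seq_len(n_hap - 1L)
        sample.int(n_hap - 1L, 1L, prob = i^(-a))
      }, 1L)
      H <- matrix(FALSE, n_sites, n_hap)
      carriers <- lapply(count, function(i) sample.int(n_hap, i))
      H[cbind(rep(seq_len(n_sites), count), unlist(carriers))] <- TRUE
      list(tbl = tibble(pos = pos, ref = ref, alt = alt, class = cls,
                        count = count),
           H = H)
    })
    structure(
      list(variants = variants, n_lines = config$n_lines, n_hap = n_hap,
           theta = config$theta, seed = seed),
      class = "line_genotypes"
    )
  })
}

# per-scaffold lookup from genomic position to codon context
.build_cds_maps <- function(reference) {
  ann <- reference$annotation
  cds <- ann[ann$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) return(list())
  maps <- list()
  for (sid in unique(cds$seqid)) {
    seg_all <- cds[cds$seqid == sid, , drop = FALSE]
    pos_list <- list()
    for (gid in unique(seg_all$gene_id)) {
      seg <- seg_all[seg_all$gene_id == gid, , drop = FALSE]
      strand <- seg$strand[1]
      seg <- seg[order(seg$start, decreasing = (strand == "-")), , drop = FALSE]
      gpos <- unlist(lapply(seq_len(nrow(seg)), function(k) {
        p <- seg$start[k]:seg$end[k]
        if (strand == "-") rev(p) else p
      }), use.names = FALSE)
      # gpos is in coding order; coding index i -> genomic position gpos[i]
      pos_list[[gid]] <- tibble(
        gpos = gpos,
        coding_index = seq_along(gpos),
        strand = strand,
        gene_id = gid
      )
    }
    tbl <- dplyr::bind_rows(pos_list)
    # where genes overlap (they do not, by construction), keep the first
    tbl <- tbl[!duplicated(tbl$gpos), , drop = FALSE]
    maps[[sid]] <- list(tbl = tbl,
                        chars = strsplit(reference$sequences[[sid]], "")[[1]])
  }
  maps
}

# classify candidate mutations as noncoding / synonymous / nonsynonymous
.classify_mutations <- function(sid, pos, alt, cds_maps) {
  cls <- rep("noncoding", length(pos))
  if (is.null(cds_maps) || is.null(cds_maps[[sid]])) return(cls)
  map <- cds_maps[[sid]]
  m <- match(pos, map$tbl$gpos)
  hit <- which(!is.na(m))
  for (k in hit) {
    row <- map$tbl[m[k], ]
    ci <- row$coding_index
    codon_idx <- (ci - 1L) %/% 3L
    offsets <- codon_idx * 3L + 1:3
    gene_tbl <- map$tbl[map$tbl$gene_id == row$gene_id, ]
    gp <- gene_tbl$gpos[offsets]
    codon <- map$chars[gp]
    alt_codon <- codon
    within <- which(gp == pos[k])
    if (row$strand == "-") {
      codon <- comp_base(codon)
      alt_codon <- codon
      alt_codon[within] <- comp_base(alt[k])
    } else {
      alt_codon[within] <- alt[k]
    }
    aa_ref <- translate_codons(paste(codon, collapse = ""))
    aa_alt <- translate_codons(paste(alt_codon, collapse = ""))
    cls[k] <- if (identical(aa_ref, aa_alt)) "synonymous" else "nonsynonymous"
  }
  cls
}

#' @export
print.line_genotypes <- function(x, ...) {
  s <- sum(vapply(x$variants, function(v) nrow(v$tbl), 1L))
  cat(sprintf("<line_genotypes> %d lines (%d haplotypes), %d segregating sites over %d scaffolds\n",
              x$n_lines, x$n_hap, s, length(x$variants)))
  invisible(x)
}

#' Materialize the haplotype alignment of one scaffold
#'
#' Returns the full `2 * n_lines` by `L` character matrix of haplotype
#' sequences (intended for small simulations and tests; storage is dense).
#'
#' @param genotypes A [simulate_line_genotypes()] result.
#' @param reference The matching [simulate_reference()] result.
#' @param scaffold Scaffold identifier.
#' @return Character matrix, rows = haplotypes.
#' @export
hap_alignment <- function(genotypes, reference, scaffold) {
  v <- genotypes$variants[[scaffold]]
  if (is.null(v)) stop_input(sprintf("unknown scaffold '%s'", scaffold))
  chars <- strsplit(reference$sequences[[scaffold]], "")[[1]]
  out <- matrix(rep(chars, each = genotypes$n_hap), nrow = genotypes$n_hap)
  if (nrow(v$tbl) > 0) {
    for (s in seq_len(nrow(v$tbl))) {
      out[v$H[s, ], v$tbl$pos[s]] <- v$tbl$alt[s]
    }
  }
  rownames(out) <- sprintf("hap_%02d", seq_len(genotypes$n_hap))
  out
}

#' Variant summary table
#'
#' @param genotypes A [simulate_line_genotypes()] result.
#' @return Tibble with one row per segregating site (scaffold, pos, ref,
#'   alt, mutation class, derived count).
#' @export
variant_table <- function(genotypes) {
  purrr::imap_dfr(genotypes$variants, function(v, sid) {
    if (nrow(v$tbl) == 0) return(NULL)
    dplyr::mutate(v$tbl, scaffold = sid, .before = 1)
  })
}
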