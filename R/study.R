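# Count-level sequencing simulation.
#
# Consensus calling only consumes the per-position counts of quality-passing
# base observations, so the study engine draws those counts directly instead
# of materializing every read: reads above and below the quality cutoff are
# independent Poisson thinnings of the per-site Poisson depth, errors among
# the retained reads are binomial, and reads at heterozygous positions split
# binomially between the two alleles.  This is distributionally identical to
# the read-level pileup generator in simulate_pileups() and feeds the same
# consensus rule (consensus_from_counts()), but runs at whole-genome scale.

OTHER_BASE_IDX <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))

# per-position observation counts for one male at the detail positions
# n: post-filter reads; e: errors among them; a1c/a2c: allele codes of the
# two chromosome copies (equal when effectively haploid); diploid: reads
# split between the two copies
.sim_counts <- function(n, e, a1c, a2c, diploid) {
  k <- length(n)
  counts <- matrix(0L, k, 4L)
  if (k == 0) return(counts)
  k1 <- ifelse(diploid, rbinom(k, n, 0.5), n)
  k2 <- n - k1
  err1 <- rhyper(k, k1, k2, e)
  err2 <- e - err1
  idx <- seq_len(k)
  counts[cbind(idx, a1c)] <- counts[cbind(idx, a1c)] + (k1 - err1)
  counts[cbind(idx, a2c)] <- counts[cbind(idx, a2c)] + (k2 - err2)
  if (sum(e) > 0) {
    row <- c(rep(idx, err1), rep(idx, err2))
    orig <- c(rep(a1c, err1), rep(a2c, err2))
    tgt <- OTHER_BASE_IDX[cbind(orig, sample.int(3L, length(row), replace = TRUE))]
    counts <- counts + matrix(tabulate((tgt - 1L) * k + row, nbins = 4L * k), k, 4L)
  }
  counts
}

# simulate one line's two males on one scaffold and call their consensus
.sim_line_scaffold <- function(ref_chars, is_x, var, line, depth, cfg,
                               majority = 0.8, focal = FALSE) {
  L <- length(ref_chars)
  h1 <- 2L * line - 1L
  h2 <- 2L * line
  lam_hi <- depth * cfg$prop_high_qual * ifelse(is_x, 0.5, 1)

  if (nrow(var$tbl) > 0) {
    rel <- var$H[, h1] | var$H[, h2]
    vpos <- var$tbl$pos[rel]
    vref <- match(var$tbl$ref[rel], BASES)
    valt <- match(var$tbl$alt[rel], BASES)
    vc <- cbind(var$H[rel, h1], var$H[rel, h2])
  } else {
    vpos <- integer(0); vref <- valt <- integer(0)
    vc <- matrix(FALSE, 0, 2)
  }
  ref_idx <- match(ref_chars, BASES)

  males <- vector("list", 2L)
  depth_mean <- c(NA_real_, NA_real_)
  for (m in 1:2) {
    nh <- rpois(L, lam_hi)
    e <- rbinom(L, nh, cfg$error_rate)
    epos <- which(e > 0L)
    P <- sort(unique(c(vpos, epos)))
    a1c <- a2c <- ref_idx[P]
    diploid <- !is_x[P]
    vi <- match(vpos, P)
    if (length(vi)) {
      x_site <- is_x[vpos]
      # autosomal sites: the male carries both haplotypes
      a1c[vi[!x_site]] <- ifelse(vc[!x_site, 1], valt[!x_site], vref[!x_site])
      a2c[vi[!x_site]] <- ifelse(vc[!x_site, 2], valt[!x_site], vref[!x_site])
      # X sites: only the haplotype this male retained
      carried <- ifelse(vc[x_site, m], valt[x_site], vref[x_site])
      a1c[vi[x_site]] <- carried
      a2c[vi[x_site]] <- carried
    }
    counts <- .sim_counts(nh[P], e[P], a1c, a2c, diploid)
    call <- rep("-", L)
    covered <- nh > 0L
    call[covered] <- ref_chars[covered]
    if (length(P)) {
      cc <- consensus_from_counts(counts, majority)
      cc[is.na(cc)] <- "-"
      call[P] <- cc
    }
    males[[m]] <- list(call = call, counts = counts, P = P, nh = nh)
    if (focal) {
      nl <- rpois(L, depth * (1 - cfg$prop_high_qual) * ifelse(is_x, 0.5, 1))
      depth_mean[m] <- (sum(nh) + sum(nl)) / L
    }
  }

  # merged line data: concatenate the two males' observations position-wise
  P_u <- sort(unique(c(males[[1]]$P, males[[2]]$P)))
  merged_counts <- matrix(0L, length(P_u), 4L)
  nh_merged <- males[[1]]$nh + males[[2]]$nh
  for (m in 1:2) {
    cm <- matrix(0L, length(P_u), 4L)
    im <- match(males[[m]]$P, P_u)
    cm[im, ] <- males[[m]]$counts
    # positions detailed only for the brother: all of this male's reads are
    # the reference base there (non-variant for the line, no errors)
    rest <- setdiff(seq_along(P_u), im)
    if (length(rest)) {
      cm[cbind(rest, ref_idx[P_u[rest]])] <- males[[m]]$nh[P_u[rest]]
    }
    merged_counts <- merged_counts + cm
  }
  merged <- rep("-", L)
  covered <- nh_merged > 0L
  merged[covered] <- ref_chars[covered]
  if (length(P_u)) {
    cc <- consensus_from_counts(merged_counts, majority)
    cc[is.na(cc)] <- "-"
    merged[P_u] <- cc
  }
  list(merged = merged,
       male1 = if (focal) males[[1]]$call,
       male2 = if (focal) males[[2]]$call,
       depth_mean = depth_mean)
}

#' Simulate a complete synthetic resequencing study
#'
#' Runs the whole generative pipeline at scale: reference and annotation,
#' line genotypes under the neutral (or skewed) site-frequency spectrum,
#' per-male sequencing at the configured depths, quality filtering,
#' consensus calling per line (males merged), brother-male difference
#' counting on the focal line, and per-scaffold / per-region diversity
#' statistics — everything downstream analyses consume, next to the hidden
#' truth labels.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @param populations Optional vector (length `n_lines`) of population
#'   labels; when given with exactly two populations, per-gene Fst is
#'   computed on the whole-gene region.
#' @param focal_line Index of the high-coverage line whose brother males
#'   drive X assignment.
#' @param compute_regions Compute per-gene region statistics (gene, CDS,
#'   UTRs, introns, flanks, synonymous/nonsynonymous site classes)?
#' @param sfs_alpha,class_spectra Passed to [simulate_line_genotypes()].
#' @param keep_consensus Keep the per-line consensus call vectors (memory
#'   heavy; intended for small runs and file export).
#' @return An `aphid_study` list: `truth`, `scaffolds` (per-scaffold panel
#'   statistics, male difference counts and focal male depths), `regions`
#'   (per-gene region statistics), `reference`, `config`, `seed`, and
#'   optionally `consensus` (list of `line_consensus`) and male call
#'   vectors.
#' @export
simulate_study <- function(config, seed = 1L, populations = NULL,
                           focal_line = 1L, compute_regions = TRUE,
                           sfs_alpha = 1, class_spectra = NULL,
                           keep_consensus = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(populations) && length(populations) != config$n_lines) {
    stop_config("`populations` must have one label per line")
  }
  reference <- simulate_reference(config, seed)
  genotypes <- simulate_line_genotypes(reference, config, seed,
                                       sfs_alpha = sfs_alpha,
                                       class_spectra = class_spectra)
  scaffold_lengths <- setNames(reference$truth$length, reference$truth$scaffold)
  regions_all <- if (compute_regions) {
    extract_regions(reference$annotation, scaffold_lengths)
  }
  segs_all <- truth_segments(reference$truth)
  pop_split <- if (!is.null(populations)) split(seq_len(config$n_lines), populations)

  local_seed(derive_seed(seed, 3L), {
    scaffold_rows <- vector("list", nrow(reference$truth))
    region_rows <- vector("list", nrow(reference$truth))
    consensus_calls <- if (keep_consensus) {
      purrr::map(seq_len(config$n_lines), function(j) list())
    }
    male_calls <- if (keep_consensus) list(male1 = list(), male2 = list())

    for (i in seq_len(nrow(reference$truth))) {
      sid <- reference$truth$scaffold[i]
      L <- reference$truth$length[i]
      ref_chars <- strsplit(reference$sequences[[sid]], "")[[1]]
      segs <- segs_all[segs_all$scaffold == sid, , drop = FALSE]
      is_x <- rep(FALSE, L)
      for (k in seq_len(nrow(segs))) {
        if (segs$seg_label[k] == "X") is_x[segs$start[k]:segs$end[k]] <- TRUE
      }
      var <- genotypes$variants[[sid]]

      calls <- vector("list", config$n_lines)
      m1 <- m2 <- NULL
      depth_mean <- c(NA_real_, NA_real_)
      for (j in seq_len(config$n_lines)) {
        focal <- j == focal_line
        d <- if (focal) config$depth_focal_male else config$depth_panel_male
        res <- .sim_line_scaffold(ref_chars, is_x, var, j, d, config,
                                  focal = focal)
        calls[[j]] <- res$merged
        if (focal) {
          m1 <- res$male1; m2 <- res$male2; depth_mean <- res$depth_mean
        }
        if (keep_consensus) consensus_calls[[j]][[sid]] <- res$merged
      }
      if (keep_consensus) {
        male_calls$male1[[sid]] <- m1
        male_calls$male2[[sid]] <- m2
      }
      aln <- do.call(rbind, calls)
      st <- diversity_stats(aln, sid)
      joint <- m1 %in% BASES & m2 %in% BASES
      n_joint <- sum(joint)
      n_diff <- sum(m1[joint] != m2[joint])
      scaffold_rows[[i]] <- tibble(
        scaffold = sid, length = L, label = reference$truth$label[i],
        L_valid = st$L_valid, S = st$S, theta_w = st$theta_w, pi = st$pi,
        tajimas_d = st$tajimas_d, coverage = st$coverage,
        n_joint = n_joint, n_diff = n_diff,
        diff_per_bp = ifelse(n_joint > 0, n_diff / n_joint, NA_real_),
        male_depth = mean(depth_mean)
      )
      if (compute_regions && !is.null(regions_all)) {
        regs <- regions_all[regions_all$scaffold == sid, , drop = FALSE]
        if (nrow(regs) > 0) {
          region_rows[[i]] <- .scaffold_region_stats(
            aln, regs, reference$truth$label[i], pop_split)
        }
      }
    }

    out <- list(
      truth = reference$truth,
      scaffolds = dplyr::bind_rows(scaffold_rows),
      regions = dplyr::bind_rows(region_rows),
      reference = reference,
      genotypes = genotypes,
      config = config,
      seed = seed,
      focal_line = focal_line,
      populations = populations
    )
    if (keep_consensus) {
      out$consensus <- purrr::map(seq_len(config$n_lines), function(j) {
        calls <- consensus_calls[[j]]
        summary <- purrr::imap_dfr(calls, function(v, s) {
          tibble(scaffold = s, length = length(v),
                 n_called = sum(v %in% BASES), n_ambiguous = sum(v == "N"),
                 ambiguous_fraction = NA_real_)
        })
        new_line_consensus(sprintf("line_%02d", j), calls, summary)
      })
      male_summary <- function(calls) {
        purrr::imap_dfr(calls, function(v, s) {
          tibble(scaffold = s, length = length(v),
                 n_called = sum(v %in% BASES), n_ambiguous = sum(v == "N"),
                 ambiguous_fraction = NA_real_)
        })
      }
      out$male_consensus <- list(
        male1 = new_line_consensus("focal_male_1", male_calls$male1,
                                   male_summary(male_calls$male1)),
        male2 = new_line_consensus("focal_male_2", male_calls$male2,
                                   male_summary(male_calls$male2))
      )
    }
    structure(out, class = "aphid_study")
  })
}

# per-gene region statistics (plus syn/nonsyn site classes and optional Fst)
.scaffold_region_stats <- function(aln, regs, scaffold_label, pop_split) {
  out <- list()
  for (gid in unique(regs$gene_id)) {
    greg <- regs[regs$gene_id == gid, , drop = FALSE]
    for (kind in unique(greg$kind)) {
      parts <- greg[greg$kind == kind, , drop = FALSE]
      sub <- region_alignment(aln, parts)
      st <- diversity_stats(sub, paste(gid, kind, sep = ":"))
      st$gene_id <- gid; st$kind <- kind
      st$scaffold <- parts$scaffold[1]; st$label <- scaffold_label
      st$fst <- NA_real_
      if (kind == "gene" && !is.null(pop_split) && length(pop_split) == 2) {
        f <- fst(sub[pop_split[[1]], , drop = FALSE],
                 sub[pop_split[[2]], , drop = FALSE])
        st$fst <- f$fst
      }
      out[[length(out) + 1L]] <- st
    }
    cds_parts <- greg[greg$kind == "cds", , drop = FALSE]
    if (nrow(cds_parts) > 0) {
      cds_aln <- region_alignment(aln, cds_parts, orient = "coding")
      if (ncol(cds_aln) %% 3 == 0) {
        cls <- classify_syn_nonsyn(cds_aln)
        for (sc in c("synonymous", "nonsynonymous")) {
          idx <- cls$site[cls$class == sc]
          st <- diversity_stats(cds_aln[, idx, drop = FALSE],
                                paste(gid, sc, sep = ":"))
          st$gene_id <- gid
          st$kind <- if (sc == "synonymous") "syn" else "nonsyn"
          st$scaffold <- cds_parts$scaffold[1]; st$label <- scaffold_label
          st$fst <- NA_real_
          out[[length(out) + 1L]] <- st
        }
      }
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.aphid_study <- function(x, ...) {
  cat(sprintf("<aphid_study> %d scaffolds (%d X, %d A, %d chimeric), %d lines, seed %d\n",
              nrow(x$scaffolds), sum(x$truth$label == "X"),
              sum(x$truth$label == "A"), sum(x$truth$label == "chimera"),
              x$config$n_lines, x$seed))
  if (nrow(x$regions) > 0) {
    cat(sprintf("  %d gene-region statistic rows\n", nrow(x$regions)))
  }
  invisible(x)
}

#' Assign scaffolds to the X or autosomes for a simulated study
#'
#' Convenience wrapper chaining the assignment steps on an
#' [simulate_study()] result: scaffold filtering, corrected differences,
#' the Student's-t mixture fit, posterior classification and the depth-ratio
#' consistency check.
#'
#' @param study An `aphid_study`.
#' @param min_length,min_S Scaffold filters (see [apply_scaffold_filters()]).
#' @param threshold Posterior classification cutoff.
#' @param ... Passed to [fit_t_mixture()].
#' @return A list: `calls` (per-scaffold tibble with cd, p_x, label and
#'   truth label), `fit`, `coverage_check`.
#' @export
assign_x_scaffolds <- function(study, min_length = 1e5, min_S = 50,
                               threshold = 0.5, ...) {
  scaff <- apply_scaffold_filters(study$scaffolds, min_length, min_S)
  diffs <- scaff |>
    dplyr::select("scaffold", "length", truth_label = "label", "S", "n_joint",
                  "n_diff", "diff_per_bp", "male_depth") |>
    dplyr::filter(.data$n_joint > 0)
  cd_tbl <- corrected_difference(diffs, scaff)
  fit <- fit_t_mixture(cd_tbl$cd, ...)
  calls <- classify_scaffolds(cd_tbl, fit, threshold)
  cov <- coverage_ratio_check(
    dplyr::transmute(calls, scaffold = .data$scaffold,
                     mean_depth = .data$male_depth),
    calls)
  list(calls = calls, fit = fit, coverage_check = cov)
}
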