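#' Merge the winged and wingless male samples of one line
#'
#' A line's two male samples are combined position-wise into a single
#' observation set before consensus calling, so each line yields one
#' (diploid, for autosomes) sequence data set.  Observation lists are simply
#' concatenated; reference bases reported at the same position must agree.
#'
#' @param ... Observation tibbles (from [pileup_observations()]), or a single
#'   list of them.
#' @return One observation tibble with all samples' reads.
#' @export
merge_male_samples <- function(...) {
  obs <- list(...)
  if (length(obs) == 1L && is.data.frame(obs[[1]]) == FALSE) obs <- obs[[1]]
  merged <- dplyr::bind_rows(obs)
  if (nrow(merged) > 0) {
    conflict <- merged |>
      dplyr::distinct(.data$scaffold, .data$pos, .data$ref) |>
      dplyr::count(.data$scaffold, .data$pos) |>
      dplyr::filter(.data$n > 1)
    if (nrow(conflict) > 0) {
      stop_input(sprintf(
        "conflicting reference bases at %d position(s), e.g. %s:%d",
        nrow(conflict), conflict$scaffold[1], conflict$pos[1]))
    }
  }
  dplyr::arrange(merged, .data$scaffold, .data$pos)
}

#' Call the consensus base of one pileup column
#'
#' Implements the line-consensus rule: only bases with Phred quality
#' strictly above `qmin` are considered; if the modal base's fraction of the
#' retained observations is strictly greater than `majority` it becomes the
#' consensus, otherwise the position is ambiguous (`"N"`).  A position with
#' no retained observations has no data (`NA`), which is distinct from `N`
#' and excluded from every downstream denominator.
#'
#' The inequalities are strict: a base at exactly Q20 is discarded and a
#' modal fraction of exactly 0.8 yields `N`.  Ties for the modal base can
#' never exceed the majority threshold, so no separate tie-break is needed.
#'
#' @param base Character vector of observed bases (A/C/G/T).
#' @param qual Integer vector of Phred qualities, parallel to `base`.
#' @param qmin Quality cutoff (strict).
#' @param majority Majority fraction cutoff (strict).
#' @return A single character: a base, `"N"`, or `NA_character_` (no data).
#' @export
call_consensus_base <- function(base, qual, qmin = 20, majority = 0.8) {
  keep <- qual > qmin
  base <- base[keep]
  if (length(base) == 0) return(NA_character_)
  counts <- tabulate(match(base, BASES), nbins = 4L)
  consensus_from_counts(matrix(counts, 1L, 4L), majority)
}

#' Vectorized consensus from per-base counts
#'
#' The count-matrix form of the consensus rule shared by the pileup path
#' and the synthetic-study generator: rows are positions, columns counts of
#' post-filter A/C/G/T observations.
#'
#' @param counts Integer matrix (positions x 4) of quality-filtered counts.
#' @param majority Majority fraction cutoff (strict).
#' @return Character vector: base, `"N"`, or `NA_character_` per row.
#' @export
consensus_from_counts <- function(counts, majority = 0.8) {
  n <- rowSums(counts)
  top <- pmax(counts[, 1], counts[, 2], counts[, 3], counts[, 4])
  call <- rep(NA_character_, nrow(counts))
  called <- n > 0 & top > majority * n
  if (any(called)) {
    call[called] <- BASES[max.col(counts[called, , drop = FALSE],
                                  ties.method = "first")]
  }
  ambiguous <- n > 0 & !called
  call[ambiguous] <- "N"
  call
}

#' Build a line's consensus sequences from merged observations
#'
#' Applies the quality and majority rules at every covered position and
#' marks uncovered positions (and positions whose observations were all
#' filtered out) as missing (`-`).
#'
#' @param obs Observation tibble (see [pileup_observations()],
#'   [merge_male_samples()]).
#' @param scaffold_lengths Named integer vector of scaffold lengths.
#' @param line_id Identifier stored with the result.
#' @param qmin,majority Consensus rule cutoffs (see [call_consensus_base()]).
#' @return A `line_consensus` object: per-scaffold call vectors over
#'   `A,C,G,T,N,-` plus a per-scaffold summary tibble (calls, ambiguous
#'   fraction, coverage).
#' @export
build_line_consensus <- function(obs, scaffold_lengths, line_id = "line",
                                 qmin = 20, majority = 0.8) {
  if (is.null(names(scaffold_lengths))) {
    stop_input("`scaffold_lengths` must be a named vector")
  }
  bad <- obs |>
    dplyr::left_join(
      tibble(scaffold = names(scaffold_lengths), .len = unname(scaffold_lengths)),
      by = "scaffold"
    ) |>
    dplyr::filter(is.na(.data$.len) | .data$pos < 1 | .data$pos > .data$.len)
  if (nrow(bad) > 0) {
    stop_input(sprintf("observation at %s:%d is outside the scaffold",
                       bad$scaffold[1], bad$pos[1]))
  }
  calls <- purrr::imap(scaffold_lengths, function(L, sid) {
    v <- rep("-", L)
    sobs <- obs[obs$scaffold == sid & obs$qual > qmin, , drop = FALSE]
    if (nrow(sobs) > 0) {
      counts <- matrix(0L, L, 4L)
      tab <- dplyr::count(sobs, .data$pos, .data$base)
      counts[cbind(tab$pos, match(tab$base, BASES))] <- tab$n
      covered <- unique(sobs$pos)
      v[covered] <- consensus_from_counts(counts[covered, , drop = FALSE],
                                          majority)
      v[is.na(v)] <- "-"
    }
    v
  })
  summary <- purrr::imap_dfr(calls, function(v, sid) {
    n_called <- sum(v %in% BASES)
    n_amb <- sum(v == "N")
    tibble(scaffold = sid, length = length(v), n_called = n_called,
           n_ambiguous = n_amb,
           ambiguous_fraction = ifelse(n_called + n_amb > 0,
                                       n_amb / (n_called + n_amb), NA_real_))
  })
  new_line_consensus(line_id, calls, summary)
}

new_line_consensus <- function(line_id, calls, summary) {
  structure(list(line_id = line_id, calls = calls, summary = summary),
            class = "line_consensus")
}

#' @export
print.line_consensus <- function(x, ...) {
  cat(sprintf("<line_consensus> %s: %d scaffolds, %.3g%% called, %.3g%% ambiguous of covered\n",
              x$line_id, nrow(x$summary),
              100 * sum(x$summary$n_called) / sum(x$summary$length),
              100 * sum(x$summary$n_ambiguous) /
                max(1, sum(x$summary$n_called) + sum(x$summary$n_ambiguous))))
  invisible(x)
}

#' Write per-line consensus sequences as FASTA
#'
#' Missing positions are written as `-`, ambiguous positions as `N`.
#'
#' @param consensus A `line_consensus` object.
#' @param path Output FASTA file.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(consensus, path) {
  seqs <- vapply(consensus$calls, paste, "", collapse = "")
  names(seqs) <- paste0(consensus$line_id, "|", names(consensus$calls))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a consensus FASTA written by [write_consensus_fasta()]
#'
#' @param path FASTA file.
#' @param line_id Line identifier; defaults to the prefix in the record names.
#' @return A `line_consensus` object.
#' @export
read_consensus_fasta <- function(path, line_id = NULL) {
  set <- Biostrings::readBStringSet(path)
  nm <- names(set)
  parts <- stringr::str_split_fixed(nm, stringr::fixed("|"), 2)
  line_id <- line_id %||% parts[1, 1]
  calls <- purrr::map(seq_along(set), function(i) {
    strsplit(as.character(set[[i]]), "")[[1]]
  })
  names(calls) <- parts[, 2]
  summary <- purrr::imap_dfr(calls, function(v, sid) {
    n_called <- sum(v %in% BASES)
    n_amb <- sum(v == "N")
    tibble(scaffold = sid, length = length(v), n_called = n_called,
           n_ambiguous = n_amb,
           ambiguous_fraction = ifelse(n_called + n_amb > 0,
                                       n_amb / (n_called + n_amb), NA_real_))
  })
  new_line_consensus(line_id, calls, summary)
}

#' Stack line consensus calls into a per-scaffold alignment matrix
#'
#' @param consensus_list List of `line_consensus` objects.
#' @param scaffold Scaffold identifier.
#' @return Character matrix, one row per line, over `A,C,G,T,N,-`.
#' @export
consensus_matrix <- function(consensus_list, scaffold) {
  rows <- purrr::map(consensus_list, function(lc) {
    v <- lc$calls[[scaffold]]
    if (is.null(v)) stop_input(sprintf("line %s lacks scaffold '%s'",
                                       lc$line_id, scaffold))
    v
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(consensus_list, function(lc) lc$line_id, "")
  out
}
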