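#' Derive a brother-male pair from one clonal line
#'
#' Males are produced asexually and are genetically identical to their
#' mother except that each has lost one of her X chromosomes.  Both brother
#' males therefore carry both autosomal haplotypes, while male 1 carries
#' only X haplotype 1 and male 2 only X haplotype 2.  On a chimeric scaffold
#' the rule applies per segment: the males match on the autosomal side of the
#' breakpoint and carry alternate haplotypes on the X side.
#'
#' @param genotypes A [simulate_line_genotypes()] result.
#' @param truth Truth tibble from [simulate_reference()].
#' @param line Line index (1-based).
#' @return A `male_pair` object describing, per scaffold segment, the
#'   haplotypes carried by each male.
#' @export
simulate_brother_males <- function(genotypes, truth, line = 1L) {
  stopifnot(inherits(genotypes, "line_genotypes"))
  if (line < 1 || line > genotypes$n_lines) stop_input("`line` out of range")
  hap1 <- 2L * line - 1L
  hap2 <- 2L * line
  segs <- truth_segments(truth)
  segs$is_x <- segs$seg_label == "X"
  structure(
    list(line = as.integer(line), hap1 = hap1, hap2 = hap2,
         segments = segs, genotypes = genotypes),
    class = "male_pair"
  )
}

#' @export
print.male_pair <- function(x, ...) {
  cat(sprintf("<male_pair> line %d (haplotypes %d/%d), %d scaffold segments (%d X-linked)\n",
              x$line, x$hap1, x$hap2, nrow(x$segments), sum(x$segments$is_x)))
  invisible(x)
}

#' Materialize one male's genome sequences for a scaffold
#'
#' Returns the set of chromosome-copy sequences the male carries on the
#' scaffold: two copies on autosomal segments (the line's two haplotypes)
#' and a single copy on X segments (the haplotype this male retained).
#' Chimeric scaffolds are returned as one row per carried copy with the
#' uncarried X haplotype's segment replaced by the carried one, so the
#' number of rows equals the autosomal copy number (copy 2 of an X segment
#' duplicates copy 1).
#'
#' @param pair A [simulate_brother_males()] result.
#' @param reference The matching [simulate_reference()] result.
#' @param scaffold Scaffold identifier.
#' @param male 1 or 2.
#' @return Character matrix with one row per chromosome copy; X segments
#'   carry an attribute `copy_number` vector (per position: 1 on X, 2 on
#'   autosomal segments).
#' @export
male_sequences <- function(pair, reference, scaffold, male = 1L) {
  segs <- pair$segments[pair$segments$scaffold == scaffold, , drop = FALSE]
  if (nrow(segs) == 0) stop_input(sprintf("unknown scaffold '%s'", scaffold))
  haps <- hap_alignment(pair$genotypes, reference, scaffold)[c(pair$hap1, pair$hap2), ,
                                                             drop = FALSE]
  carried <- if (male == 1L) 1L else 2L
  out <- haps
  copy_number <- rep(2L, ncol(haps))
  for (k in seq_len(nrow(segs))) {
    idx <- segs$start[k]:segs$end[k]
    if (segs$is_x[k]) {
      out[1, idx] <- haps[carried, idx]
      out[2, idx] <- haps[carried, idx]
      copy_number[idx] <- 1L
    }
  }
  rownames(out) <- paste0("copy_", 1:2)
  attr(out, "copy_number") <- copy_number
  out
}
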