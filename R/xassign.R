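#' Per-scaffold consensus differences between brother males
#'
#' For every scaffold, counts the positions called (an unambiguous base, not
#' `N`, not missing) in both males and, of those, the positions where the
#' calls differ.  Positions ambiguous or missing in either male are excluded
#' from both numerator and denominator.  Scaffolds with no jointly-called
#' positions are dropped, with the reason recorded in the
#' `dropped` attribute.
#'
#' @param male1,male2 `line_consensus` objects for the two brother males.
#' @return Tibble: scaffold, n_joint, n_diff, diff_per_bp; attribute
#'   `dropped` lists scaffolds without jointly-called positions.
#' @export
pairwise_male_differences <- function(male1, male2) {
  shared <- intersect(names(male1$calls), names(male2$calls))
  if (length(shared) == 0) stop_input("the two males share no scaffolds")
  rows <- purrr::map(shared, function(sid) {
    c1 <- male1$calls[[sid]]
    c2 <- male2$calls[[sid]]
    if (length(c1) != length(c2)) {
      stop_input(sprintf("scaffold '%s' has different lengths in the two males", sid))
    }
    joint <- c1 %in% BASES & c2 %in% BASES
    n_joint <- sum(joint)
    tibble(scaffold = sid, n_joint = n_joint,
           n_diff = sum(c1[joint] != c2[joint]),
           diff_per_bp = ifelse(n_joint > 0, sum(c1[joint] != c2[joint]) / n_joint,
                                NA_real_))
  })
  out <- dplyr::bind_rows(rows)
  dropped <- out$scaffold[out$n_joint == 0]
  out <- out[out$n_joint > 0, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Corrected difference scores
#'
#' Subtracts each scaffold's population diversity (per-bp pi from the full
#' line panel) from the brother-male difference rate:
#' `cd = diff_per_bp - pi`.  On an X-linked scaffold the two males carry
#' independent maternal X haplotypes, so their difference rate matches the
#' population diversity and `cd` centres near 0; on an autosomal scaffold
#' the males are genetically identical and `cd` centres near `-pi`.
#' Scaffolds without a defined pi (e.g. failing the polymorphism filter)
#' are dropped, with reasons in the `dropped` attribute.
#'
#' @param diffs Tibble from [pairwise_male_differences()].
#' @param pi_tbl Tibble with columns `scaffold` and `pi` from the line
#'   panel.
#' @return `diffs` with columns `pi` and `cd` added.
#' @export
corrected_difference <- function(diffs, pi_tbl) {
  out <- dplyr::left_join(diffs, dplyr::select(pi_tbl, "scaffold", "pi"),
                          by = "scaffold")
  dropped <- out$scaffold[is.na(out$pi)]
  out <- out[!is.na(out$pi), , drop = FALSE]
  out$cd <- out$diff_per_bp - out$pi
  attr(out, "dropped") <- c(attr(diffs, "dropped"), dropped)
  out
}

#' Filter scaffolds for X assignment
#'
#' Retains scaffolds strictly longer than `min_length` (the assignment
#' needs enough jointly-called positions to estimate a difference rate)
#' and with at least `min_S` segregating sites in the line panel (so pi is
#' estimated from real polymorphism).  Length exactly at the cutoff is
#' dropped; `S` exactly at the cutoff is kept.
#'
#' @param scaffolds Tibble with columns `length` and `S` (plus anything
#'   else, carried through).
#' @param min_length Minimum scaffold length, exclusive (bp).
#' @param min_S Minimum segregating sites, inclusive.
#' @return The retained subset.
#' @export
apply_scaffold_filters <- function(scaffolds, min_length = 1e5, min_S = 50) {
  dplyr::filter(scaffolds, .data$length > min_length,
                !is.na(.data$S), .data$S >= min_S)
}

#' Classify scaffolds from posterior X probabilities
#'
#' Labels each scaffold X when `p_x > threshold`, autosomal when
#' `p_x < threshold`, and `unresolved` at exactly the threshold.
#'
#' @param cd_tbl Tibble with columns `scaffold`, `cd` and optionally
#'   `length`.
#' @param fit A [fit_t_mixture()] result.
#' @param threshold Posterior probability cutoff.
#' @return `cd_tbl` with `p_x` and `label` columns; attribute `summary`
#'   holds per-class counts and total lengths.
#' @export
classify_scaffolds <- function(cd_tbl, fit, threshold = 0.5) {
  out <- dplyr::mutate(cd_tbl, p_x = x_probability(.data$cd, fit),
                       label = dplyr::case_when(
                         .data$p_x > threshold ~ "X",
                         .data$p_x < threshold ~ "A",
                         TRUE ~ "unresolved"
                       ))
  summary <- out |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      total_bp = if ("length" %in% names(out)) sum(.data$length) else NA_real_,
      .groups = "drop"
    )
  if ("length" %in% names(out)) {
    assigned <- out$label %in% c("A", "X")
    summary$x_fraction_of_assigned <-
      sum(out$length[out$label == "X"]) / max(1, sum(out$length[assigned]))
  }
  attr(out, "summary") <- summary
  out
}

#' Depth-ratio consistency check for predicted classes
#'
#' In males, autosomal DNA is sequenced about twice as often as X DNA
#' (two autosome copies against a single X), so the mean per-bp depth of
#' predicted autosomal scaffolds divided by that of predicted X scaffolds
#' should approach 2 when the classification is accurate; chimeric or
#' misassigned scaffolds attenuate the ratio toward 1.
#'
#' @param depth_tbl Tibble with columns `scaffold` and `mean_depth`
#'   (per-bp male read depth).
#' @param calls Tibble from [classify_scaffolds()] (columns `scaffold`,
#'   `label`).
#' @return One-row tibble: mean_depth_a, mean_depth_x, ratio (NA with a
#'   flag when a class is empty).
#' @export
coverage_ratio_check <- function(depth_tbl, calls) {
  joined <- dplyr::inner_join(depth_tbl, dplyr::select(calls, "scaffold", "label"),
                              by = "scaffold")
  mean_a <- mean(joined$mean_depth[joined$label == "A"])
  mean_x <- mean(joined$mean_depth[joined$label == "X"])
  defined <- is.finite(mean_a) && is.finite(mean_x) && mean_x > 0
  tibble(mean_depth_a = mean_a, mean_depth_x = mean_x,
         ratio = if (defined) mean_a / mean_x else NA_real_,
         defined = defined)
}

#' Cross-tabulate predicted against independently verified labels
#'
#' @param predicted Tibble with columns `scaffold`, `label` (predicted).
#' @param verified Tibble with columns `scaffold`, `label` (independent
#'   verification, e.g. RFLP genotyping).
#' @return A list: `table` (2x2 contingency, predicted x verified) and
#'   `concordance` (per predicted class, the fraction verified to match).
#' @export
verification_crosstab <- function(predicted, verified) {
  joined <- dplyr::inner_join(predicted, verified, by = "scaffold",
                              suffix = c("_pred", "_true"))
  if (nrow(joined) == 0) stop_input("no scaffolds in common between predicted and verified sets")
  tab <- table(predicted = joined$label_pred, verified = joined$label_true)
  concordance <- joined |>
    dplyr::group_by(class = .data$label_pred) |>
    dplyr::summarise(n = dplyr::n(),
                     n_concordant = sum(.data$label_pred == .data$label_true),
                     concordance = .data$n_concordant / .data$n,
                     .groups = "drop")
  list(table = tab, concordance = concordance)
}
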