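# small configurations used across test files
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_scaffolds = 6, scaffold_length = c(4000, 6000),
                   x_fraction = 0.3, theta = 0.005, n_lines = 5,
                   depth_focal_male = 8, depth_panel_male = 2,
                   gene_spacing = 4000, seed = 1)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# consensus calls as plain character vectors wrapped into line_consensus
fake_consensus <- function(line_id, calls) {
  summary <- purrr::imap_dfr(calls, function(v, s) {
    tibble::tibble(scaffold = s, length = length(v),
                   n_called = sum(v %in% c("A", "C", "G", "T")),
                   n_ambiguous = sum(v == "N"), ambiguous_fraction = NA_real_)
  })
  aphidpop:::new_line_consensus(line_id, calls, summary)
}
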