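#' Simulate a male sample's text pileup
#'
#' Per-site read counts are Poisson with mean equal to the configured
#' autosomal depth, halved on X-linked segments (males carry a single X but
#' two copies of each autosome, a 2:1 ratio in the genome).  Each read base
#' is the true haplotype base with probability `1 - error_rate`, otherwise a
#' uniformly drawn different base; read quality is one of two Phred values.
#' Positions with zero reads are omitted, as in samtools text pileups.
#'
#' @param pair A [simulate_brother_males()] result.
#' @param reference The matching [simulate_reference()] result.
#' @param male Which brother (1 or 2).
#' @param depth Mean autosomal read depth for this sample.
#' @param config A [sim_config()] supplying error and quality parameters.
#' @param seed Integer seed.
#' @param scaffolds Optional subset of scaffold ids.
#' @return A tibble with columns scaffold, pos, ref, depth, bases, quals
#'   (samtools text-pileup dialect; matches encoded as ".").
#' @export
simulate_pileups <- function(pair, reference, male = 1L, depth,
                             config, seed = 1L, scaffolds = NULL) {
  stopifnot(inherits(pair, "male_pair"))
  if (depth < 0) stop_config("`depth` must be non-negative")
  scaffolds <- scaffolds %||% names(reference$sequences)
  local_seed(derive_seed(seed, 10L + male), {
    out <- purrr::map(scaffolds, function(sid) {
      copies <- male_sequences(pair, reference, sid, male = male)
      cn <- attr(copies, "copy_number")
      L <- ncol(copies)
      ref_chars <- strsplit(reference$sequences[[sid]], "")[[1]]
      n <- rpois(L, depth * cn / 2)
      keep <- which(n > 0)
      if (length(keep) == 0) {
        return(tibble(scaffold = character(), pos = integer(), ref = character(),
                      depth = integer(), bases = character(), quals = character()))
      }
      read_pos <- rep(keep, n[keep])
      copy <- sample(1:2, length(read_pos), replace = TRUE)
      base <- copies[cbind(copy, read_pos)]
      err <- runif(length(base)) < config$error_rate
      if (any(err)) {
        base[err] <- vapply(base[err], function(b) sample(setdiff(BASES, b), 1),
                            "", USE.NAMES = FALSE)
      }
      qual <- ifelse(runif(length(base)) < config$prop_high_qual,
                     config$qual_high, config$qual_low)
      shown <- ifelse(base == ref_chars[read_pos], ".", base)
      qchar <- intToUtf8(qual + 33L, multiple = TRUE)
      tibble(
        scaffold = sid,
        pos = keep,
        ref = ref_chars[keep],
        depth = n[keep],
        bases = vapply(split(shown, factor(read_pos, levels = keep)),
                       paste, "", collapse = ""),
        quals = vapply(split(qchar, factor(read_pos, levels = keep)),
                       paste, "", collapse = "")
      )
    })
    dplyr::bind_rows(out)
  })
}

#' Write a pileup tibble as a samtools-style text pileup
#'
#' @param pileup Tibble from [simulate_pileups()] or [read_pileup()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  readr::write_tsv(pileup, path, col_names = FALSE, escape = "none")
  invisible(path)
}

#' Read a samtools text pileup
#'
#' Expects the six-column single-sample dialect: chrom, 1-based position,
#' reference base, depth, read bases, base qualities.
#'
#' @param path Pileup file.
#' @return Tibble with columns scaffold, pos, ref, depth, bases, quals.
#' @export
read_pileup <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("scaffold", "pos", "ref", "depth", "bases", "quals"),
    col_types = readr::cols(
      scaffold = readr::col_character(), pos = readr::col_integer(),
      ref = readr::col_character(), depth = readr::col_integer(),
      bases = readr::col_character(), quals = readr::col_character()
    ),
    quote = "", na = character()
  )
}

#' Decode pileup rows into per-read observations
#'
#' Strips read-start (`^` plus mapping quality), read-end (`$`) and indel
#' (`+N...`/`-N...`) marks, resolves `.`/`,` to the reference base, and
#' drops deletion placeholders (`*`), leaving one row per aligned base
#' substitution observation with its Phred quality.  Only base
#' substitutions enter the consensus rules.
#'
#' @param pileup Tibble from [read_pileup()] or [simulate_pileups()].
#' @return Tibble with columns scaffold, pos, ref, base, qual.
#' @export
pileup_observations <- function(pileup) {
  if (nrow(pileup) == 0) {
    return(tibble(scaffold = character(), pos = integer(), ref = character(),
                  base = character(), qual = integer()))
  }
  decoded <- purrr::pmap(pileup, function(scaffold, pos, ref, depth, bases, quals) {
    b <- .decode_bases(bases, ref)
    q <- utf8ToInt(quals) - 33L
    keep <- b != "*"
    tibble(scaffold = scaffold, pos = pos, ref = ref,
           base = b[keep], qual = q[keep])
  })
  dplyr::bind_rows(decoded)
}

# turn one pileup base string into a per-read base vector ("*" marks reads
# to drop); handles ^X, $, +n<seq>, -n<seq>, case and strand encodings
.decode_bases <- function(s, ref) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L            # caret plus mapping-quality char
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch %in% c("+", "-")) {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len           # skip the inserted/deleted sequence
    } else {
      base <- switch(ch,
        "." = ref, "," = ref,
        "*" = "*",
        toupper(ch)
      )
      if (!base %in% c(BASES, "*")) base <- "*"
      out <- c(out, base)
      i <- i + 1L
    }
  }
  out
}
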