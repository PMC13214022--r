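# Combinatorial barcode dictionaries.
#
# A dictionary holds `base` index variants for each of `digits` positions.
# Each index is a staggered dsDNA unit: an incoming single-stranded ligation
# overhang (6 or 7 nt, parity-matched to the digit) followed by a core
# sequence unique to the (digit, value) pair; ligation regenerates the
# opposite-parity overhang. Terminal (last-digit) indexes additionally carry
# a UMI stretch and a PCR handle.

#' Combinatorial barcode capacity
#'
#' Number of distinct codewords available from a barcode with `base` values
#' per digit and `digits` positions, i.e. `base^digits`.
#'
#' @param base Number of index variants per digit (the barcode's base `i`).
#' @param digits Number of digits `N`.
#' @return `base^digits` as a numeric scalar.
#' @examples
#' dictionary_capacity(2, 4)   # 16
#' dictionary_capacity(4, 10)  # 1,048,576 regions from 40 indexes
#' @export
dictionary_capacity <- function(base, digits) {
  base <- check_count(base, "base")
  digits <- check_count(digits, "digits")
  as.numeric(base)^as.numeric(digits)
}

#' GC fraction of a ligation overhang
#'
#' T4 DNA ligase activity on 6-7 nt single-stranded overhangs is inversely
#' correlated with GC content, so lower-GC overhangs are preferred.
#'
#' @param sequence DNA string(s) of length 6 or 7 over A/C/G/T.
#' @return GC fraction in `[0, 1]`, vectorised over `sequence`.
#' @export
score_overhang <- function(sequence) {
  if (!all(is_dna(sequence))) stop("overhang must contain only A/C/G/T")
  if (!all(nchar(sequence) %in% c(6L, 7L))) {
    stop("overhang length must be 6 or 7 nt")
  }
  gc_fraction(sequence)
}

#' Rank candidate overhangs by predicted ligation activity
#'
#' Candidates are ordered by ascending GC fraction (low GC ligates better);
#' ties are broken lexicographically so the ranking is deterministic and
#' invariant to input order.
#'
#' @param candidates Character vector of overhang sequences (each 6 or 7 nt).
#' @return The candidates, reordered best-first.
#' @export
rank_overhangs <- function(candidates) {
  gc <- score_overhang(candidates)
  candidates[order(gc, candidates)]
}

# TRUE if ligating `a`-ended molecules in the presence of `b`-overhang units
# risks cross-reaction: the reverse complement of one overhang matches the
# other (over their overlap, at any offset) with <= `max_mismatch` mismatches.
overhangs_cross_reactive <- function(a, b, max_mismatch = 1L) {
  rc <- revcomp(a)
  short <- if (nchar(rc) <= nchar(b)) rc else b
  long <- if (nchar(rc) <= nchar(b)) b else rc
  ls <- nchar(short); ll <- nchar(long)
  for (off in 0:(ll - ls)) {
    win <- substr(long, off + 1L, off + ls)
    if (str_hamming(win, short) <= max_mismatch) return(TRUE)
  }
  FALSE
}

# Rejection-sample `n` sequences of `width` nt with GC in [gc_min, gc_max],
# homopolymer runs <= max_run, and pairwise Hamming >= min_ham to each other
# and to `against`. Errors (naming the binding constraint) when the sampler
# stalls.
sample_constrained_cores <- function(n, width, min_ham, against = character(0),
                                     gc_min = 0.3, gc_max = 0.7, max_run = 3L,
                                     what = "core") {
  kept <- character(0)
  attempts <- 0L
  limit <- 2000L * max(n, 1L)
  while (length(kept) < n) {
    if (attempts >= limit) {
      stop("could not generate ", n, " ", what, " sequences of length ", width,
           ": binding constraint is pairwise Hamming distance >= ", min_ham,
           " (with GC in [", gc_min, ", ", gc_max, "], homopolymer <= ",
           max_run, ")")
    }
    batch <- max(32L, n - length(kept))
    cand <- random_dna(batch, width)
    attempts <- attempts + batch
    gc <- gc_fraction(cand)
    cand <- cand[gc >= gc_min & gc <= gc_max]
    if (length(cand)) cand <- cand[max_homopolymer(cand) <= max_run]
    for (s in cand) {
      if (length(kept) >= n) break
      pool <- c(against, kept)
      if (!length(pool) ||
          all(vapply(pool, function(k) str_hamming(k, s), integer(1)) >= min_ham)) {
        kept <- c(kept, s)
      }
    }
  }
  kept
}

# Pick the odd-acceptor (6 nt) and even-acceptor (7 nt) overhangs: sample
# low-GC candidates, rank by GC, take the best pair that is neither
# self-complementary nor cross-reactive.
pick_overhangs <- function(gc_max = 0.5) {
  cand6 <- random_dna(200L, 6L)
  cand7 <- random_dna(200L, 7L)
  keep <- function(x) {
    x <- unique(x[gc_fraction(x) <= gc_max & max_homopolymer(x) <= 3L])
    rank_overhangs(x)
  }
  cand6 <- keep(cand6)
  cand7 <- keep(cand7)
  for (a in cand6) {
    if (overhangs_cross_reactive(a, a)) next
    for (b in cand7) {
      if (overhangs_cross_reactive(b, b)) next
      if (!overhangs_cross_reactive(a, b) && !overhangs_cross_reactive(b, a)) {
        return(list(odd = a, even = b))
      }
    }
  }
  stop("could not find a non-cross-reactive overhang pair")
}

#' Build a combinatorial barcode dictionary
#'
#' Generates `base * digits` index core sequences (pairwise Hamming distance
#' at least `min_hamming` across the whole dictionary, GC between 30 and 70%,
#' homopolymer runs of at most 3) plus one odd-acceptor (6 nt) and one
#' even-acceptor (7 nt) ligation overhang screened for low GC and absence of
#' cross-complementarity. Digit 1 accepts the odd overhang; overhang parity
#' alternates along the barcode. Terminal (digit `N`) indexes carry a UMI of
#' `umi_length` nt and a shared PCR handle.
#'
#' @inheritParams dictionary_capacity
#' @param core_length Core sequence length in nt (default 10).
#' @param min_hamming Minimum pairwise Hamming distance among cores
#'   (default 3; allows single-substitution-tolerant decoding).
#' @param seed Integer seed; generation is fully deterministic given the seed.
#' @param umi_length UMI length appended by terminal indexes (nt).
#' @param handle_length PCR handle length appended by terminal indexes (nt).
#' @return An object of class `bali_dictionary`.
#' @examples
#' d <- build_dictionary(2, 4, seed = 1)
#' d
#' @export
build_dictionary <- function(base, digits, core_length = 10L, min_hamming = 3L,
                             seed = 1L, umi_length = 10L, handle_length = 20L) {
  base <- check_count(base, "base")
  digits <- check_count(digits, "digits")
  core_length <- check_count(core_length, "core_length")
  min_hamming <- check_count(min_hamming, "min_hamming")
  if (min_hamming > core_length) {
    stop("infeasible: min_hamming (", min_hamming,
         ") exceeds core_length (", core_length,
         ") -- binding constraint is core_length")
  }
  n_cores <- base * digits
  if (4^core_length < n_cores) {
    stop("infeasible: alphabet admits only 4^", core_length,
         " distinct cores but ", n_cores,
         " are required -- binding constraint is core_length")
  }
  with_seed(seed, {
    oh <- pick_overhangs()
    cores <- sample_constrained_cores(n_cores, core_length, min_hamming)
    handle <- random_dna(1L, handle_length)
    idx <- expand.grid(value = 0:(base - 1L), digit = 1:digits)[, 2:1]
    idx <- idx[order(idx$digit, idx$value), , drop = FALSE]
    rownames(idx) <- NULL
    idx$core <- cores
    idx$is_terminal <- idx$digit == digits
    idx$umi_length <- ifelse(idx$is_terminal, as.integer(umi_length), 0L)
    idx$handle <- ifelse(idx$is_terminal, handle, "")
    structure(
      list(base = base, digits = digits, min_hamming = min_hamming,
           core_length = core_length,
           overhangs = list(odd = oh$odd, even = oh$even),
           umi_length = as.integer(umi_length), handle = handle,
           indexes = idx),
      class = "bali_dictionary")
  })
}

#' @export
print.bali_dictionary <- function(x, ...) {
  cat("Barcode dictionary: base", x$base, "x", x$digits, "digits",
      sprintf("(capacity %s)\n",
              format(dictionary_capacity(x$base, x$digits), big.mark = ",")))
  cat("  overhangs: odd-acceptor", x$overhangs$odd,
      "| even-acceptor", x$overhangs$even, "\n")
  cat("  cores:", nrow(x$indexes), "x", x$core_length,
      "nt, min pairwise Hamming", x$min_hamming, "\n")
  cat("  terminal digit adds", x$umi_length, "nt UMI +",
      nchar(x$handle), "nt handle\n")
  invisible(x)
}

# Core lookup: the core for (digit, value).
dict_core <- function(dict, digit, value) {
  dict$indexes$core[dict$indexes$digit == digit & dict$indexes$value == value]
}

# Incoming overhang sequence for a digit (parity-matched).
dict_overhang <- function(dict, digit) {
  if (digit %% 2L == 1L) dict$overhangs$odd else dict$overhangs$even
}

# Length of the sequenced unit for a digit: incoming overhang + core.
dict_unit_length <- function(dict, digit) {
  nchar(dict_overhang(dict, digit)) + dict$core_length
}

dict_unit <- function(dict, digit, value) {
  paste0(dict_overhang(dict, digit), dict_core(dict, digit, value))
}

#' Validate a barcode dictionary
#'
#' Diagnostic check of the structural invariants: core uniqueness, intra-digit
#' Hamming distance, alternating overhang parity (one 6 nt, one 7 nt,
#' different lengths), and overhang cross-complementarity (an overhang pair is
#' flagged when one's reverse complement matches the other within 1 mismatch).
#'
#' @param dict A `bali_dictionary`.
#' @return A data frame of violations with columns `check` and `detail`;
#'   zero rows iff the dictionary is valid.
#' @export
validate_dictionary <- function(dict) {
  stopifnot(inherits(dict, "bali_dictionary"))
  bad <- list()
  note <- function(check, detail) {
    bad[[length(bad) + 1L]] <<- data.frame(check = check, detail = detail)
  }
  idx <- dict$indexes
  dup <- duplicated(idx$core) | duplicated(idx$core, fromLast = TRUE)
  if (any(dup)) {
    for (core in unique(idx$core[dup])) {
      keys <- idx[idx$core == core, , drop = FALSE]
      note("core_uniqueness",
           paste0("core ", core, " shared by ",
                  paste(sprintf("(%d,%d)", keys$digit, keys$value),
                        collapse = " and ")))
    }
  }
  for (d in unique(idx$digit)) {
    cores <- idx$core[idx$digit == d]
    if (length(cores) > 1L) {
      for (i in seq_len(length(cores) - 1L)) for (j in (i + 1):length(cores)) {
        h <- str_hamming(cores[i], cores[j])
        if (h < dict$min_hamming) {
          note("intra_digit_hamming",
               sprintf("digit %d values %d/%d at Hamming %d < %d",
                       d, i - 1L, j - 1L, h, dict$min_hamming))
        }
      }
    }
  }
  lo <- nchar(dict$overhangs$odd); le <- nchar(dict$overhangs$even)
  if (!all(c(lo, le) %in% c(6L, 7L)) || lo == le) {
    note("overhang_parity",
         sprintf("overhang lengths %d/%d must be one 6 nt and one 7 nt", lo, le))
  }
  pairs <- list(c("odd", "odd"), c("odd", "even"), c("even", "even"))
  for (p in pairs) {
    a <- dict$overhangs[[p[1L]]]; b <- dict$overhangs[[p[2L]]]
    if (overhangs_cross_reactive(a, b)) {
      note("overhang_cross_reactivity",
           sprintf("%s-acceptor vs %s-acceptor: reverse complement within 1 mismatch",
                   p[1L], p[2L]))
    }
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(check = character(0), detail = character(0))
}

#' Write a dictionary to JSON
#'
#' Serialisation is byte-reproducible: keys are written in a fixed order.
#'
#' @param dict A `bali_dictionary`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "bali_dictionary"))
  obj <- list(
    base = dict$base, digits = dict$digits, min_hamming = dict$min_hamming,
    core_length = dict$core_length,
    overhangs = list(
      list(sequence = dict$overhangs$odd, parity = "odd"),
      list(sequence = dict$overhangs$even, parity = "even")),
    umi_length = dict$umi_length, handle = dict$handle,
    indexes = lapply(seq_len(nrow(dict$indexes)), function(i) {
      r <- dict$indexes[i, ]
      list(digit = r$digit, value = r$value, core = r$core,
           is_terminal = r$is_terminal, umi_length = r$umi_length,
           handle = r$handle)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a dictionary from JSON
#'
#' @param path File written by [write_dictionary()].
#' @return A `bali_dictionary`.
#' @export
read_dictionary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  idx <- do.call(rbind, lapply(obj$indexes, function(r) {
    data.frame(digit = as.integer(r$digit), value = as.integer(r$value),
               core = r$core, is_terminal = isTRUE(r$is_terminal),
               umi_length = as.integer(r$umi_length), handle = r$handle)
  }))
  oh <- setNames(
    vapply(obj$overhangs, function(o) o$sequence, character(1)),
    vapply(obj$overhangs, function(o) o$parity, character(1)))
  structure(
    list(base = as.integer(obj$base), digits = as.integer(obj$digits),
         min_hamming = as.integer(obj$min_hamming),
         core_length = as.integer(obj$core_length),
         overhangs = list(odd = unname(oh[["odd"]]), even = unname(oh[["even"]])),
         umi_length = as.integer(obj$umi_length), handle = obj$handle,
         indexes = idx),
    class = "bali_dictionary")
}
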