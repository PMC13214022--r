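# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

# n random DNA strings of the given width (column-wise paste keeps this
# vectorised for populations of 1e5+).
random_dna <- function(n, width) {
  if (n == 0L) return(character(0))
  cols <- lapply(seq_len(width), function(i) sample(DNA_BASES, n, replace = TRUE))
  do.call(paste0, cols)
}

# Vectorised GC fraction over {A,C,G,T} strings.
gc_fraction <- function(x) {
  nchar(gsub("[^GCgc]", "", x)) / nchar(x)
}

is_dna <- function(x) {
  grepl("^[ACGT]+$", x)
}

# Hamming distance between two equal-length strings.
str_hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# Hamming distance of each of `windows` (all nchar == nchar(unit)) to `unit`.
# Byte-matrix comparison; the workhorse of the decoder.
hamming_to <- function(windows, unit) {
  if (!length(windows)) return(integer(0))
  L <- nchar(unit)
  m <- matrix(charToRaw(paste(windows, collapse = "")), nrow = L)
  as.integer(colSums(m != charToRaw(unit)))
}

max_homopolymer <- function(x) {
  vapply(x, function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
    max(r$lengths)
  }, integer(1), USE.NAMES = FALSE)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Substitution sequencing errors on a character vector of reads (fixed or
# variable width). Operates on one concatenated raw vector for speed.
apply_substitutions <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  widths <- nchar(reads)
  big <- paste(reads, collapse = "")
  r <- charToRaw(big)
  hit <- which(runif(length(r)) < rate)
  if (length(hit)) {
    cur <- rawToChar(r[hit], multiple = TRUE)
    # substitute with a uniformly chosen *different* base
    repl <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L),
                   character(1), USE.NAMES = FALSE)
    r[hit] <- charToRaw(paste(repl, collapse = ""))
  }
  big <- rawToChar(r)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  substring(big, starts, ends)
}

digit_parity <- function(k) ifelse(k %% 2L == 1L, "odd", "even")

digitset_key <- function(members) paste(members, collapse = ",")

key_to_members <- function(key) {
  if (identical(key, "")) return(integer(0))
  as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
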