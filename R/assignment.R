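# Region -> codeword assignment.
#
# Codewords are length-N integer vectors with values in [0, base). The
# sequential strategy enumerates codewords in mixed-radix order with digit 1
# as the least-significant position.

# t (0-based) -> codeword row, digit 1 least significant.
codeword_from_rank <- function(t, base, digits) {
  vapply(seq_len(digits), function(n) (t %/% base^(n - 1L)) %% base,
         numeric(length(t)))
}

codeword_key <- function(cw) {
  if (is.null(dim(cw))) cw <- matrix(cw, nrow = 1L)
  apply(cw, 1L, paste, collapse = "")
}

#' Assign barcodes to regions
#'
#' Maps every region of a region map to a distinct codeword from the
#' dictionary's `base^digits` codeword space.
#'
#' @param region_map A `bali_region_map`.
#' @param dict A `bali_dictionary`.
#' @param strategy `"sequential"` (codewords in mixed-radix order, digit 1
#'   least significant), `"seeded-random"` (a seeded random sample of distinct
#'   codewords), or `"max-distance"` (greedy maximisation of the minimum
#'   pairwise codeword Hamming distance, ties broken lexicographically).
#' @param seed Seed for the `"seeded-random"` strategy.
#' @return A `bali_assignment`: region labels plus an integer codeword matrix
#'   (regions x digits, values 0-based).
#' @export
assign_barcodes <- function(region_map, dict,
                            strategy = c("sequential", "seeded-random",
                                         "max-distance"),
                            seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(region_map, "bali_region_map"),
            inherits(dict, "bali_dictionary"))
  labels <- region_map$regions$label
  r <- length(labels)
  capacity <- dictionary_capacity(dict$base, dict$digits)
  if (r > capacity) {
    need <- if (dict$base == 1L) Inf else ceiling(log(r) / log(dict$base))
    stop(r, " regions exceed capacity ", capacity, " (base ", dict$base,
         ", ", dict$digits, " digits); ", need, " digits required")
  }
  cw <- switch(strategy,
    "sequential" = codeword_from_rank(seq_len(r) - 1, dict$base, dict$digits),
    "seeded-random" = with_seed(seed, {
      ranks <- sample.int(capacity, r) - 1
      codeword_from_rank(ranks, dict$base, dict$digits)
    }),
    "max-distance" = maxdist_codewords(r, dict$base, dict$digits))
  if (is.null(dim(cw))) cw <- matrix(cw, nrow = r)
  cw <- matrix(as.integer(cw), nrow = r)
  structure(list(labels = labels, codewords = cw,
                 base = dict$base, digits = dict$digits),
            class = "bali_assignment")
}

# Greedy farthest-point selection over the full codeword space; deterministic
# (lexicographic tie-break). Enumeration bounded to keep memory sane.
maxdist_codewords <- function(r, base, digits) {
  capacity <- base^digits
  if (capacity > 2^16) {
    stop("max-distance strategy enumerates the codeword space; capacity ",
         capacity, " too large (use sequential or seeded-random)")
  }
  all_cw <- codeword_from_rank(0:(capacity - 1), base, digits)
  if (is.null(dim(all_cw))) all_cw <- matrix(all_cw, ncol = digits)
  chosen <- 1L  # lexicographically smallest codeword (all zeros)
  mind <- rowSums(all_cw != matrix(all_cw[1L, ], capacity, digits, byrow = TRUE))
  while (length(chosen) < r) {
    mind[chosen] <- -1L
    best <- which(mind == max(mind))[1L]  # ties: lowest rank = lex order
    chosen <- c(chosen, best)
    d <- rowSums(all_cw != matrix(all_cw[best, ], capacity, digits, byrow = TRUE))
    mind <- pmin(mind, d)
  }
  all_cw[chosen, , drop = FALSE]
}

#' @export
print.bali_assignment <- function(x, ...) {
  cat("Barcode assignment:", length(x$labels), "regions, base", x$base,
      "x", x$digits, "digits\n")
  invisible(x)
}

#' Write an assignment to JSON
#' @param assignment A `bali_assignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path) {
  obj <- list(base = assignment$base, digits = assignment$digits,
              labels = assignment$labels,
              codewords = lapply(seq_along(assignment$labels), function(i)
                as.integer(assignment$codewords[i, ])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read an assignment from JSON
#' @param path File written by [write_assignment()].
#' @return A `bali_assignment`.
#' @export
read_assignment <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(labels = as.integer(obj$labels),
                 codewords = matrix(as.integer(t(obj$codewords)),
                                    nrow = length(obj$labels), byrow = TRUE),
                 base = as.integer(obj$base), digits = as.integer(obj$digits)),
            class = "bali_assignment")
}
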