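# Parity automaton over barcode digits.
#
# Index ligation alternates between two orthogonal overhangs: digit 1 ligates
# onto the root's odd-accepting overhang and every successful ligation flips
# the exposed acceptor type. A partial barcode is therefore chemically
# reachable iff its first digit is odd and consecutive members alternate
# parity; only molecules carrying the terminal digit (which appends the UMI
# and PCR handle) ever appear in sequencing.

#' Enumerate chemically reachable digit sets
#'
#' Returns every set of digit positions that the alternating-overhang ligation
#' chemistry can produce on a single molecule: starting from an odd-accepting
#' root, a digit can ligate only when its parity matches the exposed acceptor,
#' and each success flips the acceptor parity. Equivalently, the sets
#' `d1 < d2 < ... < dm` with `d1` odd and consecutive members of alternating
#' parity, plus the empty set.
#'
#' @param digits Number of digits `N` in the barcode (positive integer).
#' @return A list of strictly increasing integer vectors (the empty set is
#'   `integer(0)`), ordered by set size then lexicographically.
#' @examples
#' enumerate_reachable_digit_sets(4)  # 8 sets, e.g. {3,4} but never {1,3}
#' @export
enumerate_reachable_digit_sets <- function(digits) {
  digits <- check_count(digits, "digits")
  acc <- list(integer(0))
  recurse <- function(last, set) {
    if (last + 1L > digits) return(invisible())
    nxt <- seq.int(last + 1L, digits, by = 2L)
    for (d in nxt) {
      s <- c(set, d)
      acc[[length(acc) + 1L]] <<- s
      recurse(d, s)
    }
  }
  if (digits >= 1L) recurse(0L, integer(0))
  ord <- order(lengths(acc),
               vapply(acc, function(s) paste(sprintf("%04d", s), collapse = ""),
                      character(1)))
  acc[ord]
}

#' Digit sets observable in sequencing
#'
#' Reachable digit sets that contain the terminal digit. Only the last-cycle
#' index carries the unique molecular identifier and the PCR handle, so
#' molecules missing the terminal digit are never amplified and yield no
#' sequencing read.
#'
#' @inheritParams enumerate_reachable_digit_sets
#' @return A list of integer vectors, each containing `digits`.
#' @export
observable_digit_sets <- function(digits) {
  digits <- check_count(digits, "digits")
  sets <- enumerate_reachable_digit_sets(digits)
  Filter(function(s) length(s) > 0L && s[length(s)] == digits, sets)
}

#' Test whether a digit set is chemically reachable
#'
#' @param members Integer vector of digit positions (a set; need not be
#'   sorted).
#' @param digits Number of digits `N`.
#' @return `TRUE` iff the set can be produced by the alternating-overhang
#'   ligation automaton.
#' @examples
#' is_reachable(c(3, 4), 4)  # TRUE: first ligation failed, 3 and 4 succeeded
#' is_reachable(c(1, 3), 4)  # FALSE: after digit 1 the acceptor is even
#' @export
is_reachable <- function(members, digits) {
  digits <- check_count(digits, "digits")
  members <- as.integer(members)
  if (anyNA(members)) stop("digit set contains NA")
  if (any(members < 1L) || any(members > digits)) {
    stop("digit set member out of range [1, ", digits, "]")
  }
  if (anyDuplicated(members)) return(FALSE)
  members <- sort(members)
  if (!length(members)) return(TRUE)
  if (members[1L] %% 2L != 1L) return(FALSE)
  if (length(members) == 1L) return(TRUE)
  all(diff(members %% 2L) != 0L)
}

check_count <- function(x, what) {
  if (length(x) != 1L || is.na(x) || x < 1 || x != as.integer(x)) {
    stop("`", what, "` must be a positive integer")
  }
  as.integer(x)
}
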