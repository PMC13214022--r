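# Closed-form digit-set distribution under the parity automaton, and yield
# forecasting. The complete-barcode fraction is the product of the per-cycle
# ligation efficiencies, so yield decays exponentially in the number of
# digits.

#' Per-cycle ligation efficiency model
#'
#' @param p Scalar per-cycle ligation efficiency, or a vector `p_1..p_N`.
#' @param digits Number of digits `N` (required when `p` is scalar).
#' @return A `bali_efficiency_model`.
#' @export
efficiency_model <- function(p, digits = length(p)) {
  digits <- check_count(digits, "digits")
  p <- as.numeric(p)
  if (length(p) == 1L) p <- rep(p, digits)
  if (length(p) != digits) stop("`p` must have length 1 or `digits`")
  if (any(p < 0 | p > 1)) stop("efficiencies must lie in [0, 1]")
  structure(list(p = p, digits = digits), class = "bali_efficiency_model")
}

#' @export
print.bali_efficiency_model <- function(x, ...) {
  cat("Ligation efficiency model:", x$digits, "digits, p =",
      paste(sprintf("%.3f", x$p), collapse = " "), "\n")
  cat(sprintf("  complete-barcode yield: %.4f\n", cumulative_yield(x)))
  invisible(x)
}

#' Cumulative complete-barcode yield
#'
#' The fraction of molecules carrying all `N` digits: the product of the
#' per-cycle efficiencies (`p^N` for a scalar efficiency).
#'
#' @param model A `bali_efficiency_model` (or a numeric efficiency vector).
#' @return Probability in `[0, 1]`.
#' @examples
#' cumulative_yield(efficiency_model(0.648^(1 / 3), 5))   # ~0.485
#' cumulative_yield(efficiency_model(0.648^(1 / 3), 10))  # ~0.235
#' @export
cumulative_yield <- function(model) {
  if (is.numeric(model)) model <- efficiency_model(model)
  stopifnot(inherits(model, "bali_efficiency_model"))
  prod(model$p)
}

#' Digit-set distribution under the parity automaton
#'
#' Walks the ligation automaton with success probability `p_k` at each
#' parity-eligible digit and accumulates the probability of every reachable
#' digit set. The observable distribution renormalises over the sets that
#' contain the terminal digit (the only molecules that amplify and sequence).
#'
#' @param model A `bali_efficiency_model`.
#' @return List with named probability vectors `reachable` (sums to 1) and
#'   `observable` (conditional on carrying the terminal digit); names are
#'   comma-joined digit sets (`""` = empty set).
#' @export
digit_set_probabilities <- function(model) {
  if (is.numeric(model)) model <- efficiency_model(model)
  stopifnot(inherits(model, "bali_efficiency_model"))
  p <- model$p
  N <- model$digits
  keys <- character(0)
  probs <- numeric(0)
  rec <- function(last, prob, set) {
    elig <- if (last + 1L > N) integer(0) else seq.int(last + 1L, N, by = 2L)
    cumfail <- 1
    for (e in elig) {
      rec(e, prob * cumfail * p[e], c(set, e))
      cumfail <- cumfail * (1 - p[e])
    }
    keys[length(keys) + 1L] <<- digitset_key(set)
    probs[length(probs) + 1L] <<- prob * cumfail
  }
  rec(0L, 1, integer(0))
  reachable <- setNames(probs, keys)
  term <- vapply(keys, function(k) {
    m <- key_to_members(k)
    length(m) > 0L && m[length(m)] == N
  }, logical(1))
  observable <- reachable[term] / sum(reachable[term])
  list(reachable = reachable, observable = observable)
}

#' Yield forecast over barcode lengths
#'
#' For a scalar per-cycle efficiency, tabulates the complete-barcode yield
#' `p^N` and the combinatorial capacity `base^N` over a range of digit
#' counts.
#'
#' @param p Scalar per-cycle ligation efficiency.
#' @param digit_range Integer vector of digit counts `N`.
#' @param base Barcode base for the capacity column.
#' @return Data frame with columns `digits`, `yield`, `capacity`.
#' @examples
#' forecast_table(0.648^(1 / 3), c(5, 10), base = 2)
#' @export
forecast_table <- function(p, digit_range = 1:12, base = 2L) {
  if (length(p) != 1L || p < 0 || p > 1) {
    stop("`p` must be a scalar probability")
  }
  base <- check_count(base, "base")
  digit_range <- vapply(digit_range, check_count, integer(1), what = "digits")
  data.frame(digits = digit_range,
             yield = p^digit_range,
             capacity = as.numeric(base)^digit_range)
}

#' Simulate an observed barcode spectrum
#'
#' Draws molecule counts over reachable digit sets from the closed-form
#' distribution and returns the observable part (sets containing the terminal
#' digit), mimicking what sequencing of an experiment with `molecules`
#' molecules would tally.
#'
#' @param model A `bali_efficiency_model`.
#' @param molecules Total number of molecules.
#' @param seed Integer seed.
#' @return Named integer vector of counts over observable digit sets.
#' @export
simulate_spectrum <- function(model, molecules = 1e5, seed = 1L) {
  if (is.numeric(model)) model <- efficiency_model(model)
  dsp <- digit_set_probabilities(model)
  counts <- with_seed(seed, {
    as.integer(rmultinom(1L, as.integer(molecules), dsp$reachable))
  })
  names(counts) <- names(dsp$reachable)
  counts[names(dsp$observable)]
}
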