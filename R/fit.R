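# Maximum-likelihood recovery of per-cycle ligation efficiencies from an
# observed barcode spectrum.
#
# The data are multinomial counts over the observable digit sets (those
# containing the terminal digit); category probabilities come from the parity
# automaton conditioned on observability, which matches the data-generating
# process (unamplified molecules are never sequenced) and avoids a latent
# total-count nuisance parameter.

#' Fit per-cycle ligation efficiencies to a barcode spectrum
#'
#' Maximises the multinomial likelihood of the observed digit-set counts
#' under the parity-automaton model. Three constraints are supported:
#' `"scalar"` (a single shared efficiency), `"shared-bulk"` (a free first
#' cycle `p_1` plus one shared efficiency for cycles 2..N, reflecting the
#' commonly depressed first ligation), and `"free"` (all `p_k`; refused when
#' the observable categories cannot identify that many parameters — for
#' `N = 4` there are only 3 observable categories).
#'
#' Optimisation is on logit-transformed probabilities from 5 deterministic
#' starting points (BFGS, relative log-likelihood tolerance 1e-8); standard
#' errors come from the observed information, delta-transformed to the
#' probability scale. Estimates on the boundary (e.g. a spectrum that is 100%
#' complete) are flagged and reported without standard errors.
#'
#' @param counts Named counts over observable digit sets (names are
#'   comma-joined digit positions, e.g. `"1,2,3,4"`), or a data frame with
#'   columns `digit_set` and `count`.
#' @param digits Number of digits `N`.
#' @param constraint `"scalar"`, `"shared-bulk"` or `"free"`.
#' @return A `bali_fit` with [coef()], [summary()], [logLik()], [vcov()],
#'   [predict()], [residuals()], [simulate()] and [plot()] methods.
#' @examples
#' sp <- simulate_spectrum(efficiency_model(0.9, 4), 1e5, seed = 1)
#' fit <- fit_per_cycle(sp, digits = 4, constraint = "scalar")
#' coef(fit)
#' @export
fit_per_cycle <- function(counts, digits,
                          constraint = c("scalar", "shared-bulk", "free")) {
  constraint <- match.arg(constraint)
  digits <- check_count(digits, "digits")
  if (is.data.frame(counts)) {
    counts <- setNames(counts$count, counts$digit_set)
  }
  obs_sets <- vapply(observable_digit_sets(digits), digitset_key, character(1))
  extra <- setdiff(names(counts), obs_sets)
  if (length(extra)) {
    stop("spectrum contains unobservable digit sets: ",
         paste(extra, collapse = ", "))
  }
  y <- setNames(rep(0, length(obs_sets)), obs_sets)
  y[names(counts)] <- as.numeric(counts)
  if (sum(y) <= 0) stop("spectrum is empty")
  k <- length(obs_sets)
  npar <- switch(constraint, scalar = 1L, `shared-bulk` = 2L, free = digits)
  if (npar > k - 1L) {
    stop("constraint '", constraint, "' has ", npar, " parameters but only ",
         k, " observable categories (", k - 1L,
         " degrees of freedom) for N = ", digits,
         "; use 'scalar' or 'shared-bulk'")
  }
  degenerate <- sum(y > 0) == 1L
  p_of <- function(theta) {
    pr <- plogis(theta)
    switch(constraint,
           scalar = rep(pr, digits),
           `shared-bulk` = c(pr[1L], rep(pr[2L], digits - 1L)),
           free = pr)
  }
  nll <- function(theta) {
    q <- digit_set_probabilities(efficiency_model(p_of(theta)))$observable
    q <- pmax(q[obs_sets], 1e-300)
    -sum(y * log(q))
  }
  starts <- c(0.3, 0.5, 0.7, 0.85, 0.95)
  best <- NULL
  for (s in starts) {
    fit <- try(optim(rep(qlogis(s), npar), nll, method = "BFGS",
                     control = list(reltol = 1e-8, maxit = 500)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value - 1e-10) best <- fit
  }
  if (is.null(best)) stop("optimisation failed from all starting points")
  p_hat <- p_of(best$par)
  boundary <- degenerate || any(p_hat > 1 - 1e-6) || any(p_hat < 1e-6)
  se <- rep(NA_real_, npar)
  vc <- matrix(NA_real_, npar, npar)
  if (!boundary) {
    H <- try(optimHess(best$par, nll), silent = TRUE)
    if (!inherits(H, "try-error")) {
      vc_logit <- try(solve(H), silent = TRUE)
      if (!inherits(vc_logit, "try-error")) {
        pr <- plogis(best$par)
        J <- diag(pr * (1 - pr), npar)  # d p / d logit
        vc <- J %*% vc_logit %*% J
        se <- sqrt(pmax(diag(vc), 0))
      }
    }
  }
  par_names <- switch(constraint,
                      scalar = "p",
                      `shared-bulk` = c("p1", "p_bulk"),
                      free = paste0("p", seq_len(digits)))
  dimnames(vc) <- list(par_names, par_names)
  structure(list(p = p_hat, par = setNames(plogis(best$par), par_names),
                 se = setNames(se, par_names), vcov = vc,
                 constraint = constraint, digits = digits,
                 counts = y, logLik = -best$value,
                 convergence = best$convergence, boundary = boundary),
            class = "bali_fit")
}

#' @export
print.bali_fit <- function(x, ...) {
  cat("Per-cycle ligation efficiency fit (", x$constraint, ", N = ",
      x$digits, ")\n", sep = "")
  est <- rbind(estimate = x$par, std.error = x$se)
  print(round(est, 4))
  if (x$boundary) cat("Note: estimate on the boundary; standard errors",
                      "unavailable\n")
  cat(sprintf("log-likelihood: %.2f on %d reads\n", x$logLik, sum(x$counts)))
  invisible(x)
}

#' @export
coef.bali_fit <- function(object, ...) object$par

#' @export
logLik.bali_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$par), class = "logLik")
}

#' @export
vcov.bali_fit <- function(object, ...) object$vcov

#' @export
summary.bali_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$par, std.error = object$se)
  fitted <- predict(object, type = "spectrum")
  n <- sum(object$counts)
  structure(list(coefficients = tab, constraint = object$constraint,
                 digits = object$digits, logLik = object$logLik,
                 boundary = object$boundary,
                 spectrum = data.frame(digit_set = names(object$counts),
                                       observed = as.numeric(object$counts) / n,
                                       fitted = as.numeric(fitted)),
                 yield = cumulative_yield(efficiency_model(object$p))),
            class = "summary.bali_fit")
}

#' @export
print.summary.bali_fit <- function(x, ...) {
  cat("Per-cycle ligation efficiency fit (", x$constraint, ", N = ",
      x$digits, ")\n\nCoefficients:\n", sep = "")
  print(round(x$coefficients, 4))
  cat("\nObservable spectrum (fractions):\n")
  print(transform(x$spectrum, observed = round(observed, 4),
                  fitted = round(fitted, 4)), row.names = FALSE)
  cat(sprintf("\nImplied complete-barcode yield: %.4f\n", x$yield))
  if (x$boundary) cat("Note: estimate on the boundary\n")
  invisible(x)
}

#' Predicted spectrum or yield from a fitted efficiency model
#'
#' @param object A `bali_fit`.
#' @param type `"spectrum"` (conditional probabilities over observable digit
#'   sets) or `"yield"` (complete-barcode fraction, optionally over
#'   `digit_range` for scalar fits).
#' @param digit_range Digit counts for `type = "yield"` extrapolation.
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
predict.bali_fit <- function(object, type = c("spectrum", "yield"),
                             digit_range = object$digits, ...) {
  type <- match.arg(type)
  if (type == "spectrum") {
    dsp <- digit_set_probabilities(efficiency_model(object$p))
    return(dsp$observable[names(object$counts)])
  }
  if (object$constraint == "scalar") {
    setNames(object$par[["p"]]^digit_range, digit_range)
  } else {
    setNames(cumulative_yield(efficiency_model(object$p)), object$digits)
  }
}

#' @export
residuals.bali_fit <- function(object, ...) {
  n <- sum(object$counts)
  q <- predict(object, type = "spectrum")
  (as.numeric(object$counts) - n * q) / sqrt(n * q * (1 - q))
}

#' Simulate spectra from a fitted efficiency model
#'
#' @param object A `bali_fit`.
#' @param nsim Number of spectra.
#' @param seed Integer seed.
#' @param molecules Molecules per simulated spectrum.
#' @param ... Unused.
#' @return A list of named count vectors over observable digit sets.
#' @export
simulate.bali_fit <- function(object, nsim = 1L, seed = 1L,
                              molecules = sum(object$counts), ...) {
  model <- efficiency_model(object$p)
  lapply(seq_len(nsim), function(i) {
    simulate_spectrum(model, molecules, seed = seed + i - 1L)
  })
}

#' @export
plot.bali_fit <- function(x, ...) {
  n <- sum(x$counts)
  obs <- as.numeric(x$counts) / n
  fit <- as.numeric(predict(x, type = "spectrum"))
  m <- rbind(observed = obs, fitted = fit)
  colnames(m) <- names(x$counts)
  graphics::barplot(m, beside = TRUE, legend.text = TRUE,
                    ylab = "fraction of observable reads",
                    xlab = "digit set", ...)
  invisible(x)
}

#' Ratio of first- vs second-ligation failures
#'
#' For a 4-digit barcode, molecules that fail the first ligation but complete
#' digits 3 and 4 appear as the `{3,4}` partial barcode, while molecules that
#' fail the second appear as `{1,4}`. Their count ratio equals
#' `((1 - p1) p3) / (p1 (1 - p2))`; multiplying by `p1 / p3` (when per-cycle
#' estimates are available) converts it into the failure-rate ratio
#' `(1 - p1) / (1 - p2)`.
#'
#' @param spectrum Named counts over digit sets (must contain `"3,4"` and
#'   `"1,4"`), or a data frame with columns `digit_set` and `count`.
#' @param p_estimates Optional per-cycle efficiency estimates `p_1..p_4` used
#'   to apply the `p1 / p3` correction.
#' @return The (optionally corrected) ratio; `NA` with a warning when the
#'   `{1,4}` count is zero.
#' @export
infer_first_vs_second_failure_ratio <- function(spectrum, p_estimates = NULL) {
  if (is.data.frame(spectrum)) {
    spectrum <- setNames(spectrum$count, spectrum$digit_set)
  }
  c34 <- if ("3,4" %in% names(spectrum)) as.numeric(spectrum[["3,4"]]) else 0
  c14 <- if ("1,4" %in% names(spectrum)) as.numeric(spectrum[["1,4"]]) else 0
  if (c14 == 0) {
    warning("no {1,4} partial barcodes observed; ratio undefined")
    return(NA_real_)
  }
  ratio <- c34 / c14
  if (!is.null(p_estimates)) {
    ratio <- ratio * p_estimates[1L] / p_estimates[3L]
  }
  ratio
}
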