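# Stochastic forward model of uncaging + ligation.
#
# Molecules start caged with an odd-accepting root. At each illumination
# step a molecule is eligible iff its region is illuminated or a background
# uncaging event occurs (probability beta per molecule per step). An eligible
# caged molecule is uncaged; an eligible uncaged molecule whose exposed
# acceptor parity matches the step's digit ligates that digit's index with
# probability p_digit, recording the step's value, flipping parity and
# re-caging (terminal ligations instead draw a UMI). Only molecules carrying
# the terminal digit are amplifiable and emit reads.

#' Simulation configuration
#'
#' @param efficiencies Per-digit ligation success probability: a scalar `p`
#'   or a vector `p_1..p_N`.
#' @param background_uncaging Probability of a spurious uncaging event per
#'   molecule per illumination step (default 0.018).
#' @param molecules_per_region Molecules seeded per region (default 1000).
#' @param seq_error_rate Substitution probability per sequenced base
#'   (default 0.001).
#' @param read1_length,read2_length Read lengths in nt (defaults 100 and 200:
#'   read-1 maps the molecule, read-2 decodes the spatial barcode).
#' @param umi_length UMI length in nt (default 10).
#' @param modality `"RNA"`, `"ATAC"` or `"multiome"` (an equal mix).
#' @param abundance Optional transcript abundance weights: a named numeric
#'   vector applied to every region, or a list of such vectors keyed by
#'   region label (RNA mode).
#' @param seed Integer seed driving all randomness of the simulation.
#' @return A `bali_sim_config`.
#' @export
sim_config <- function(efficiencies = 0.86, background_uncaging = 0.018,
                       molecules_per_region = 1000L, seq_error_rate = 0.001,
                       read1_length = 100L, read2_length = 200L,
                       umi_length = 10L,
                       modality = c("RNA", "ATAC", "multiome"),
                       abundance = NULL, seed = 1L) {
  modality <- match.arg(modality)
  probs <- c(efficiencies, background_uncaging, seq_error_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(efficiencies = efficiencies,
                 background_uncaging = background_uncaging,
                 molecules_per_region = as.integer(molecules_per_region),
                 seq_error_rate = seq_error_rate,
                 read1_length = as.integer(read1_length),
                 read2_length = as.integer(read2_length),
                 umi_length = as.integer(umi_length),
                 modality = modality, abundance = abundance,
                 seed = seed),
            class = "bali_sim_config")
}

expand_efficiencies <- function(efficiencies, digits) {
  p <- as.numeric(efficiencies)
  if (length(p) == 1L) p <- rep(p, digits)
  if (length(p) != digits) {
    stop("efficiency vector has length ", length(p), " but protocol has ",
         digits, " digits")
  }
  p
}

#' Initialise a molecule population
#'
#' Seeds `molecules_per_region` molecules in every region of the map. RNA
#' molecules draw a transcript (uniformly, or from the configured abundance
#' weights); ATAC molecules draw a fragment from an accessible interval of
#' the toy genome. All molecules start caged with an odd-accepting root and
#' no ligated digits.
#'
#' @param region_map A `bali_region_map`.
#' @param config A `bali_sim_config`.
#' @param reference A `bali_reference`.
#' @return A `bali_population`.
#' @export
init_molecules <- function(region_map, config, reference) {
  stopifnot(inherits(region_map, "bali_region_map"),
            inherits(config, "bali_sim_config"),
            inherits(reference, "bali_reference"))
  if (config$modality %in% c("RNA", "multiome") &&
      !length(reference$transcripts)) {
    stop("RNA modality requested but reference has no transcripts")
  }
  if (config$modality %in% c("ATAC", "multiome") &&
      !nrow(reference$accessible)) {
    stop("ATAC modality requested but reference has no accessible intervals")
  }
  if (config$molecules_per_region < 1L) {
    stop("molecules_per_region must be positive")
  }
  labels <- region_map$regions$label
  n <- length(labels) * config$molecules_per_region
  region <- rep(labels, each = config$molecules_per_region)
  with_seed(config$seed, {
    modality <- switch(config$modality,
      RNA = rep("RNA", n),
      ATAC = rep("ATAC", n),
      multiome = sample(c("RNA", "ATAC"), n, replace = TRUE))
    feature <- character(n)
    frag_start <- rep(NA_integer_, n)
    frag_width <- rep(NA_integer_, n)
    is_rna <- modality == "RNA"
    if (any(is_rna)) {
      tx <- names(reference$transcripts)
      for (lab in labels) {
        sel <- is_rna & region == lab
        if (!any(sel)) next
        w <- region_abundance(config$abundance, lab, tx)
        feature[sel] <- sample(tx, sum(sel), replace = TRUE, prob = w)
      }
    }
    if (any(!is_rna)) {
      k <- sum(!is_rna)
      iv <- sample.int(nrow(reference$accessible), k, replace = TRUE)
      acc <- reference$accessible
      width <- pmin(150L, acc$end[iv] - acc$start[iv] + 1L)
      off <- floor(runif(k) * (acc$end[iv] - acc$start[iv] + 2L - width))
      feature[!is_rna] <- acc$name[iv]
      frag_start[!is_rna] <- acc$start[iv] + as.integer(off)
      frag_width[!is_rna] <- width
    }
    structure(list(n = n, region = region, modality = modality,
                   feature = feature, frag_start = frag_start,
                   frag_width = frag_width,
                   values = matrix(NA_integer_, n, 0L),
                   last = rep(0L, n), caged = rep(TRUE, n),
                   umi = rep(NA_character_, n), steps_applied = 0L,
                   digits = NA_integer_),
              class = "bali_population")
  })
}

region_abundance <- function(abundance, label, tx) {
  if (is.null(abundance)) return(NULL)
  w <- if (is.list(abundance)) abundance[[as.character(label)]] else abundance
  if (is.null(w)) return(NULL)
  if (is.null(names(w)) || !all(names(w) %in% tx)) {
    stop("abundance weights must be named by transcript")
  }
  out <- setNames(rep(0, length(tx)), tx)
  out[names(w)] <- w
  out
}

#' @export
print.bali_population <- function(x, ...) {
  cat("Molecule population:", x$n, "molecules,",
      length(unique(x$region)), "regions;", x$steps_applied,
      "steps applied\n")
  invisible(x)
}

# Core step update, shared by apply_step() and run_protocol().
# `illuminated_regions`: labels whose pixels the step mask covers.
step_population <- function(pop, digit, value, illuminated_regions, p_digit,
                            beta, umi_length, terminal) {
  if (ncol(pop$values) == 0L) {
    stop("population not bound to a protocol; use run_protocol() or ",
         "apply_step()")
  }
  illuminated <- pop$region %in% illuminated_regions
  eligible <- illuminated | (beta > 0 & runif(pop$n) < beta)
  # uncage eligible caged molecules
  pop$caged <- pop$caged & !eligible
  # ligation: eligible, uncaged, parity-matched, digit beyond last ligated
  can <- eligible & !pop$caged &
    ((pop$last + 1L) %% 2L == digit %% 2L) & (digit > pop$last)
  succ <- can & runif(pop$n) < p_digit
  if (any(succ)) {
    pop$values[succ, digit] <- value
    pop$last[succ] <- digit
    if (terminal) {
      pop$umi[succ] <- random_dna(sum(succ), umi_length)
    } else {
      pop$caged[succ] <- TRUE  # regenerated overhang arrives photocaged
    }
  }
  pop$steps_applied <- pop$steps_applied + 1L
  pop
}

#' Apply one illumination/ligation step
#'
#' Advances the population through step `step_index` of the compiled plan.
#' Randomness is drawn from the current RNG state; [run_protocol()] seeds it
#' once from the configuration.
#'
#' @param pop A `bali_population`.
#' @param plan A `bali_protocol`.
#' @param step_index Which step of the plan to apply.
#' @param config A `bali_sim_config`.
#' @return The updated population.
#' @export
apply_step <- function(pop, plan, step_index, config) {
  stopifnot(inherits(pop, "bali_population"),
            inherits(plan, "bali_protocol"),
            inherits(config, "bali_sim_config"))
  digits <- plan$dict$digits
  if (ncol(pop$values) == 0L) {
    pop$values <- matrix(NA_integer_, pop$n, digits)
    pop$digits <- digits
  }
  p <- expand_efficiencies(config$efficiencies, digits)
  s <- plan$steps[step_index, ]
  step_population(pop, s$digit, s$value, plan$regions_per_step[[step_index]],
                  p[s$digit], config$background_uncaging, config$umi_length,
                  terminal = s$digit == digits)
}

#' Run a full barcoding protocol
#'
#' Initialises the population and applies every step of the plan in order,
#' then tallies the per-region digit-set spectrum.
#'
#' @param plan A `bali_protocol`.
#' @param config A `bali_sim_config`.
#' @param reference A `bali_reference`.
#' @return A `bali_run`: list with `population` and `spectrum` (data frame of
#'   region, digit_set, count).
#' @export
run_protocol <- function(plan, config, reference) {
  stopifnot(inherits(plan, "bali_protocol"))
  pop <- init_molecules(plan$region_map, config, reference)
  digits <- plan$dict$digits
  pop$values <- matrix(NA_integer_, pop$n, digits)
  pop$digits <- digits
  p <- expand_efficiencies(config$efficiencies, digits)
  pop <- with_seed(config$seed + 1L, {
    for (i in seq_len(nrow(plan$steps))) {
      s <- plan$steps[i, ]
      pop <- step_population(pop, s$digit, s$value, plan$regions_per_step[[i]],
                             p[s$digit], config$background_uncaging,
                             config$umi_length,
                             terminal = s$digit == digits)
    }
    pop
  })
  structure(list(population = pop, spectrum = population_spectrum(pop),
                 plan = plan, config = config, reference = reference),
            class = "bali_run")
}

#' @export
print.bali_run <- function(x, ...) {
  full <- digitset_key(seq_len(x$population$digits))
  sp <- x$spectrum
  frac <- sum(sp$count[sp$digit_set == full]) / sum(sp$count)
  cat("Simulated run:", x$population$n, "molecules,",
      sprintf("complete-barcode fraction %.3f\n", frac))
  invisible(x)
}

# Digit-set key per molecule, vectorised ("1,3,4" style; "" = empty set).
population_digitsets <- function(pop) {
  pieces <- lapply(seq_len(ncol(pop$values)), function(n) {
    ifelse(is.na(pop$values[, n]), "", paste0(n, ","))
  })
  sub(",$", "", do.call(paste0, pieces))
}

#' Digit-set spectrum of a population
#'
#' @param pop A `bali_population` that has been run through a protocol.
#' @return Data frame with columns `region`, `digit_set` (comma-joined digit
#'   positions, `""` for none) and `count`.
#' @export
population_spectrum <- function(pop) {
  ds <- population_digitsets(pop)
  agg <- aggregate(list(count = rep(1L, pop$n)),
                   by = list(region = pop$region, digit_set = ds), FUN = sum)
  agg[order(agg$region, -agg$count), , drop = FALSE]
}

#' Simulate a bulk ligation extension ladder
#'
#' Bulk-mode analogue of the bead densitometry assay: every molecule is
#' illuminated at every cycle, and the number of successful ligations per
#' molecule is tallied. The full-length fraction converges to the product of
#' the per-cycle efficiencies.
#'
#' @param p Per-cycle efficiency vector `p_1..p_N` (or scalar with `digits`).
#' @param molecules Number of molecules.
#' @param seed Integer seed.
#' @param digits Number of cycles when `p` is scalar.
#' @return Named numeric vector: fraction of molecules with `0..N` ligations.
#' @export
simulate_extension_ladder <- function(p, molecules = 1e5, seed = 1L,
                                      digits = length(p)) {
  if (length(p) == 1L) p <- rep(p, digits)
  n <- as.integer(molecules)
  with_seed(seed, {
    last <- rep(0L, n)
    count <- rep(0L, n)
    for (k in seq_along(p)) {
      elig <- (last + 1L) %% 2L == k %% 2L
      succ <- elig & runif(n) < p[k]
      last[succ] <- k
      count[succ] <- count[succ] + 1L
    }
    tab <- tabulate(count + 1L, nbins = length(p) + 1L)
    setNames(tab / n, 0:length(p))
  })
}
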