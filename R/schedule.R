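# Protocol compilation: one illumination + ligation step per (digit, value).
#
# During the step for (digit n, value i) every region whose codeword has
# value i at digit n is illuminated, uncaging its molecules for ligation of
# that index. Steps are ordered digit-major, value-minor, giving exactly
# base x digits steps per protocol.

#' Compile an illumination/ligation schedule
#'
#' @param assignment A `bali_assignment`.
#' @param dict The `bali_dictionary` the assignment was made from.
#' @param region_map The `bali_region_map` the assignment covers.
#' @param minutes_per_step Ligation cycle duration in minutes (default 90).
#' @param overhead_minutes_per_step Per-step fluidics/imaging overhead in
#'   minutes (default 9, so a 20-step protocol takes about 33 h).
#' @return A `bali_protocol` with a step table (`step_index`, `digit`,
#'   `value`) and, per step, the labels of the illuminated regions.
#' @export
compile_schedule <- function(assignment, dict, region_map,
                             minutes_per_step = 90,
                             overhead_minutes_per_step = 9) {
  stopifnot(inherits(assignment, "bali_assignment"),
            inherits(dict, "bali_dictionary"),
            inherits(region_map, "bali_region_map"))
  if (assignment$base != dict$base || assignment$digits != dict$digits) {
    stop("assignment and dictionary disagree on base/digits")
  }
  if (!all(assignment$labels %in% region_map$regions$label)) {
    stop("assignment refers to regions absent from the region map")
  }
  steps <- expand.grid(value = 0:(dict$base - 1L), digit = 1:dict$digits)
  steps <- steps[order(steps$digit, steps$value), c("digit", "value")]
  steps <- data.frame(step_index = seq_len(nrow(steps)), steps,
                      row.names = NULL)
  regions_per_step <- lapply(seq_len(nrow(steps)), function(i) {
    assignment$labels[assignment$codewords[, steps$digit[i]] == steps$value[i]]
  })
  structure(list(steps = steps, regions_per_step = regions_per_step,
                 assignment = assignment, dict = dict,
                 region_map = region_map,
                 minutes_per_step = minutes_per_step,
                 overhead_minutes_per_step = overhead_minutes_per_step),
            class = "bali_protocol")
}

#' @export
print.bali_protocol <- function(x, ...) {
  cat("Illumination protocol:", nrow(x$steps), "steps (base", x$dict$base,
      "x", x$dict$digits, "digits),", length(x$assignment$labels),
      "regions\n")
  cat("  estimated duration:", estimate_duration(x), "minutes\n")
  invisible(x)
}

#' Render per-step photomasks
#'
#' One binary raster per step: the union of the pixels of all regions whose
#' codeword carries the step's value at the step's digit. Within a digit the
#' value masks are pairwise disjoint and together cover every assigned pixel;
#' background is never illuminated.
#'
#' @param plan A `bali_protocol`.
#' @return A list of logical matrices, one per step, named
#'   `step_<index>_d<digit>_v<value>`.
#' @export
render_masks <- function(plan) {
  stopifnot(inherits(plan, "bali_protocol"))
  labels <- plan$region_map$labels
  masks <- lapply(seq_len(nrow(plan$steps)), function(i) {
    m <- matrix(labels %in% plan$regions_per_step[[i]],
                nrow(labels), ncol(labels))
    m
  })
  names(masks) <- sprintf("step_%d_d%d_v%d", plan$steps$step_index,
                          plan$steps$digit, plan$steps$value)
  masks
}

#' Estimated protocol duration
#'
#' `(minutes_per_step + overhead_minutes_per_step) * number of steps`. With
#' the defaults (90 + 9 min) a 20-step protocol takes 1,980 min, about 33 h.
#'
#' @param plan A `bali_protocol`.
#' @return Duration in minutes.
#' @export
estimate_duration <- function(plan) {
  stopifnot(inherits(plan, "bali_protocol"))
  if (plan$minutes_per_step <= 0) stop("step duration must be positive")
  (plan$minutes_per_step + plan$overhead_minutes_per_step) * nrow(plan$steps)
}

#' Export a protocol plan to a directory
#'
#' Writes `plan.json` (step table and durations, stable key order),
#' `dictionary.json`, `assignment.json`, `labels.tif`, and one binary PNG
#' photomask per step named `step_<index>_d<digit>_v<value>.png`.
#'
#' @param plan A `bali_protocol`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_protocol <- function(plan, dir) {
  stopifnot(inherits(plan, "bali_protocol"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  masks <- render_masks(plan)
  mask_files <- paste0(names(masks), ".png")
  for (i in seq_along(masks)) {
    png::writePNG(masks[[i]] * 1, file.path(dir, mask_files[i]))
  }
  write_label_image(plan$region_map$labels, file.path(dir, "labels.tif"))
  write_dictionary(plan$dict, file.path(dir, "dictionary.json"))
  write_assignment(plan$assignment, file.path(dir, "assignment.json"))
  obj <- list(
    dictionary_ref = "dictionary.json",
    assignment_ref = "assignment.json",
    labels_ref = "labels.tif",
    pixel_size = plan$region_map$pixel_size,
    minutes_per_step = plan$minutes_per_step,
    overhead_minutes_per_step = plan$overhead_minutes_per_step,
    steps = lapply(seq_len(nrow(plan$steps)), function(i) {
      list(step_index = plan$steps$step_index[i],
           digit = plan$steps$digit[i], value = plan$steps$value[i],
           mask_file = mask_files[i])
    }))
  jsonlite::write_json(obj, file.path(dir, "plan.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Import a protocol plan from a directory
#'
#' @param dir Directory written by [export_protocol()].
#' @return A `bali_protocol`.
#' @export
import_protocol <- function(dir) {
  obj <- jsonlite::read_json(file.path(dir, "plan.json"),
                             simplifyVector = FALSE)
  dict <- read_dictionary(file.path(dir, obj$dictionary_ref))
  assignment <- read_assignment(file.path(dir, obj$assignment_ref))
  labels <- read_label_image(file.path(dir, obj$labels_ref))
  rm <- new_region_map(labels, obj$pixel_size)
  compile_schedule(assignment, dict, rm,
                   minutes_per_step = obj$minutes_per_step,
                   overhead_minutes_per_step = obj$overhead_minutes_per_step)
}
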