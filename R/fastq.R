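# Synthetic paired-end read emission.
#
# Read layout (shared with the decoder):
#   read-1: RNA  -> first `read1_length` nt of the transcript;
#           ATAC -> 19-nt Tn5 mosaic end + fragment prefix;
#           padded with A to the read length.
#   read-2: in ligation order, (incoming overhang + core) for every ligated
#           index, then the UMI, then the PCR handle, padded with A (or
#           truncated) to `read2_length`.
# Only molecules carrying the terminal digit (UMI + handle) emit a pair.

#' Emit paired FASTQ from a simulated run
#'
#' Writes `R1.fastq`, `R2.fastq` and a truth table `truth.tsv` (read name,
#' region, modality, feature, digit set, UMI). Read names encode the molecule
#' id. Substitution sequencing errors are applied at the configured rate;
#' output is byte-identical under a fixed seed.
#'
#' @param run A `bali_run` from [run_protocol()] (or a fully stepped
#'   `bali_population` via the `population`/`plan` arguments of the
#'   internals).
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with the emitted read count and file paths.
#' @export
emit_fastq <- function(run, dir) {
  stopifnot(inherits(run, "bali_run"))
  pop <- run$population
  plan <- run$plan
  config <- run$config
  reference <- run$reference
  if (pop$steps_applied < nrow(plan$steps)) {
    stop("population has only ", pop$steps_applied, " of ",
         nrow(plan$steps), " steps applied; run the full protocol first")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dict <- plan$dict
  N <- dict$digits
  sel <- which(!is.na(pop$values[, N]))  # amplifiable: terminal digit present
  r1_path <- file.path(dir, "R1.fastq")
  r2_path <- file.path(dir, "R2.fastq")
  truth_path <- file.path(dir, "truth.tsv")
  if (!length(sel)) {
    file.create(r1_path, r2_path)
    write.table(data.frame(read = character(0)), truth_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(invisible(list(n_reads = 0L, r1 = r1_path, r2 = r2_path,
                          truth = truth_path)))
  }
  reads <- with_seed(config$seed + 2L, {
    r2 <- build_read2(pop, sel, dict, config)
    r1 <- build_read1(pop, sel, reference, config)
    list(r1 = apply_substitutions(r1, config$seq_error_rate),
         r2 = apply_substitutions(r2, config$seq_error_rate))
  })
  names_ <- sprintf("mol%08d", sel)
  write_fastq(setNames(reads$r1, names_), r1_path)
  write_fastq(setNames(reads$r2, names_), r2_path)
  truth <- data.frame(read = names_, region = pop$region[sel],
                      modality = pop$modality[sel],
                      feature = pop$feature[sel],
                      digit_set = population_digitsets(pop)[sel],
                      umi = pop$umi[sel])
  write.table(truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(n_reads = length(sel), r1 = r1_path, r2 = r2_path,
                 truth = truth_path))
}

build_read2 <- function(pop, sel, dict, config) {
  N <- dict$digits
  pieces <- lapply(seq_len(N), function(n) {
    v <- pop$values[sel, n]
    out <- character(length(sel))
    lig <- !is.na(v)
    if (any(lig)) {
      units <- vapply(0:(dict$base - 1L), function(val) dict_unit(dict, n, val),
                      character(1))
      out[lig] <- units[v[lig] + 1L]
    }
    out
  })
  body <- paste0(do.call(paste0, pieces), pop$umi[sel], dict$handle)
  pad_to(body, config$read2_length)
}

build_read1 <- function(pop, sel, reference, config) {
  L <- config$read1_length
  out <- character(length(sel))
  mod <- pop$modality[sel]
  rna <- mod == "RNA"
  if (any(rna)) {
    out[rna] <- substr(reference$transcripts[pop$feature[sel][rna]], 1L, L)
  }
  if (any(!rna)) {
    i <- sel[!rna]
    frag <- substr(rep(reference$genome, length(i)), pop$frag_start[i],
                   pop$frag_start[i] + pop$frag_width[i] - 1L)
    me <- reference$mosaic_end
    out[!rna] <- substr(paste0(me, frag), 1L, L)
  }
  pad_to(out, L)
}

pad_to <- function(x, width) {
  x <- substr(x, 1L, width)
  short <- nchar(x) < width
  if (any(short)) {
    x[short] <- paste0(x[short], strrep("A", width - nchar(x[short])))
  }
  x
}

# FASTQ writing/reading through Biostrings (constant "I" qualities).
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads)
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

read_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(dna), names(dna))
}
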