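# Toy sequencing references for the read simulator: a set of poly-adenylated
# transcripts (RNA mode) and a small genome with annotated accessible
# intervals (ATAC mode). ATAC inserts are flanked by the 19-nt Tn5 mosaic
# end recognition sequence.

MOSAIC_END <- "AGATGTGTATAAGAGACAG"

#' Build a toy reference
#'
#' Generates random transcript sequences (with a poly-A tail) and a random
#' toy genome with non-overlapping accessible (open-chromatin) intervals.
#' Transcript 5' prefixes are kept pairwise-distinct over the first
#' `min_read1_match` nucleotides used by the decoder.
#'
#' @param n_transcripts Number of toy transcripts.
#' @param transcript_length Transcript body length (nt), before the poly-A
#'   tail.
#' @param polya_length Poly-A tail length (nt).
#' @param genome_length Toy genome length (nt).
#' @param n_accessible Number of accessible intervals.
#' @param accessible_width Width of each accessible interval (nt).
#' @param seed Integer seed.
#' @return A `bali_reference` with elements `transcripts` (named character
#'   vector), `genome` (single string), `accessible` (data frame with
#'   `name`, `start`, `end`; 1-based inclusive) and `mosaic_end`.
#' @export
make_toy_reference <- function(n_transcripts = 8L, transcript_length = 300L,
                               polya_length = 20L, genome_length = 20000L,
                               n_accessible = 10L, accessible_width = 400L,
                               seed = 1L) {
  stopifnot(n_transcripts >= 1L, transcript_length >= 120L,
            genome_length >= n_accessible * accessible_width)
  with_seed(seed, {
    bodies <- character(0)
    while (length(bodies) < n_transcripts) {
      cand <- random_dna(n_transcripts - length(bodies), transcript_length)
      pref <- substr(cand, 1L, 30L)
      keep <- !(pref %in% substr(bodies, 1L, 30L)) & !duplicated(pref)
      bodies <- c(bodies, cand[keep])
    }
    transcripts <- paste0(bodies, strrep("A", polya_length))
    names(transcripts) <- sprintf("tx%02d", seq_len(n_transcripts))
    genome <- random_dna(1L, genome_length)
    # evenly spaced, non-overlapping accessible intervals
    gap <- (genome_length - n_accessible * accessible_width) %/% (n_accessible + 1L)
    starts <- gap + (0:(n_accessible - 1L)) * (accessible_width + gap) + 1L
    accessible <- data.frame(name = sprintf("open%02d", seq_len(n_accessible)),
                             start = as.integer(starts),
                             end = as.integer(starts + accessible_width - 1L))
    structure(list(transcripts = transcripts, genome = genome,
                   accessible = accessible, mosaic_end = MOSAIC_END),
              class = "bali_reference")
  })
}

#' @export
print.bali_reference <- function(x, ...) {
  cat("Toy reference:", length(x$transcripts), "transcripts,",
      nchar(x$genome), "nt genome with", nrow(x$accessible),
      "accessible intervals\n")
  invisible(x)
}

#' Write a toy reference to a directory
#'
#' Writes `transcripts.fa`, `genome.fa` (FASTA) and `accessible.bed`
#' (0-based half-open BED).
#'
#' @param reference A `bali_reference`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_reference <- function(reference, dir) {
  stopifnot(inherits(reference, "bali_reference"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tx <- Biostrings::DNAStringSet(reference$transcripts)
  Biostrings::writeXStringSet(tx, file.path(dir, "transcripts.fa"))
  g <- Biostrings::DNAStringSet(setNames(reference$genome, "toy_genome"))
  Biostrings::writeXStringSet(g, file.path(dir, "genome.fa"))
  bed <- data.frame(chrom = "toy_genome",
                    start = reference$accessible$start - 1L,
                    end = reference$accessible$end,
                    name = reference$accessible$name)
  write.table(bed, file.path(dir, "accessible.bed"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a toy reference from a directory
#'
#' @param dir Directory written by [write_reference()].
#' @return A `bali_reference`.
#' @export
read_reference <- function(dir) {
  tx <- Biostrings::readDNAStringSet(file.path(dir, "transcripts.fa"))
  g <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  bed <- read.table(file.path(dir, "accessible.bed"), sep = "\t",
                    col.names = c("chrom", "start", "end", "name"))
  structure(list(transcripts = setNames(as.character(tx), names(tx)),
                 genome = unname(as.character(g)[1L]),
                 accessible = data.frame(name = bed$name,
                                         start = as.integer(bed$start + 1L),
                                         end = as.integer(bed$end)),
                 mosaic_end = MOSAIC_END),
            class = "bali_reference")
}
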