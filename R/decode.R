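# Barcode demultiplexing.
#
# Read-2 is parsed greedily left to right. At each position the automaton
# constrains the candidate units to digits beyond the last call with the
# correct acceptor parity; all such units share one overhang, so they are
# distinguished by their cores (pairwise Hamming >= min_hamming across the
# dictionary). A unique unit within the mismatch tolerance is accepted and
# the parser advances by the unit length; two units within tolerance make
# the read ambiguous; none ends the barcode (UMI/handle region). Parsing the
# terminal digit also extracts the UMI.

#' Decoder configuration
#'
#' @param max_mismatches_per_index Maximum Hamming distance to accept a unit
#'   call (default 1; must stay below the dictionary's `min_hamming` for
#'   unambiguous nearest-core calls).
#' @param umi_collapse `"exact"` (default) or `"single-mismatch"` (greedy
#'   directional clustering of UMIs within Hamming distance 1).
#' @param min_read1_match Number of leading read-1 nucleotides that must match
#'   a reference prefix exactly for feature assignment (default 30).
#' @return A `bali_decode_config`.
#' @export
decode_config <- function(max_mismatches_per_index = 1L,
                          umi_collapse = c("exact", "single-mismatch"),
                          min_read1_match = 30L) {
  umi_collapse <- match.arg(umi_collapse)
  structure(list(max_mismatches_per_index = as.integer(max_mismatches_per_index),
                 umi_collapse = umi_collapse,
                 min_read1_match = as.integer(min_read1_match)),
            class = "bali_decode_config")
}

#' Classify a decoded digit set
#'
#' @param members Integer vector of called digit positions.
#' @param digits Number of digits `N` (or a `bali_dictionary`).
#' @return `"complete"` (all `N` digits), `"reachable-partial"` (an
#'   observable incomplete barcode) or `"invalid"` (chemically unreachable or
#'   unamplifiable).
#' @examples
#' classify_call(c(1, 4), 4)  # "reachable-partial"
#' classify_call(c(2, 4), 4)  # "invalid": barcodes cannot start even
#' @export
classify_call <- function(members, digits) {
  if (inherits(digits, "bali_dictionary")) digits <- digits$digits
  digits <- check_count(digits, "digits")
  members <- sort(as.integer(members))
  if (length(members) == digits && all(members == seq_len(digits))) {
    return("complete")
  }
  if (!length(members)) return("invalid")
  ok <- all(members >= 1L) && all(members <= digits) &&
    is_reachable(members, digits) && members[length(members)] == digits
  if (ok) "reachable-partial" else "invalid"
}

#' Call index digits from a spatial read
#'
#' Parses a single read-2 sequence against the dictionary (see the module
#' description for the greedy automaton-constrained parse).
#'
#' @param read2 Read-2 DNA string.
#' @param dict A `bali_dictionary`.
#' @param config A `bali_decode_config`.
#' @return List with `calls` (data frame of digit, value), `digit_set`,
#'   `classification`, and `umi` (NA unless the terminal digit was called).
#' @export
call_indices <- function(read2, dict, config = decode_config()) {
  res <- decode_reads2(read2, dict, config)
  vals <- res$values[1L, ]
  called <- which(!is.na(vals))
  list(calls = data.frame(digit = called, value = vals[called]),
       digit_set = called,
       classification = res$classification[1L],
       umi = res$umi[1L])
}

# Vectorised greedy parser over a character vector of read-2 sequences.
decode_reads2 <- function(reads, dict, config) {
  n <- length(reads)
  N <- dict$digits
  maxmm <- config$max_mismatches_per_index
  if (maxmm >= dict$min_hamming) {
    stop("max_mismatches_per_index (", maxmm, ") must be below the ",
         "dictionary min_hamming (", dict$min_hamming, ")")
  }
  values <- matrix(NA_integer_, n, N)
  umi <- rep(NA_character_, n)
  pos <- rep(1L, n)
  last <- rep(0L, n)
  state <- rep("active", n)
  min_len <- dict_unit_length(dict, 1L) + dict$umi_length
  state[nchar(reads) < min_len] <- "short"
  repeat {
    act <- which(state == "active")
    if (!length(act)) break
    progressed <- FALSE
    for (par in c(1L, 0L)) {  # parity of the next acceptor: odd = 1
      idx <- act[state[act] == "active" & (last[act] + 1L) %% 2L == par]
      if (!length(idx)) next
      cand_digits <- seq_len(N)[seq_len(N) %% 2L == par]
      L <- dict_unit_length(dict, cand_digits[1L])
      win <- substr(reads[idx], pos[idx], pos[idx] + L - 1L)
      full <- nchar(win) == L
      nhit <- integer(length(idx))
      hit_digit <- integer(length(idx))
      hit_value <- integer(length(idx))
      for (d in cand_digits) {
        for (v in 0:(dict$base - 1L)) {
          mm <- rep(Inf, length(idx))
          if (any(full)) mm[full] <- hamming_to(win[full], dict_unit(dict, d, v))
          ok <- mm <= maxmm & d > last[idx]
          nhit <- nhit + ok
          hit_digit[ok] <- d
          hit_value[ok] <- v
        }
      }
      amb <- nhit >= 2L
      none <- nhit == 0L
      one <- nhit == 1L
      state[idx[amb]] <- "ambiguous"
      state[idx[none]] <- "done"
      if (any(one)) {
        progressed <- TRUE
        i1 <- idx[one]
        d1 <- hit_digit[one]
        values[cbind(i1, d1)] <- hit_value[one]
        pos[i1] <- pos[i1] + L
        last[i1] <- d1
        term <- d1 == N
        if (any(term)) {
          it <- i1[term]
          umi[it] <- substr(reads[it], pos[it], pos[it] + dict$umi_length - 1L)
          state[it] <- "done"
        }
      }
    }
    if (!progressed) break
  }
  classification <- character(n)
  for (i in seq_len(n)) {
    classification[i] <- if (state[i] == "ambiguous") {
      "ambiguous"
    } else if (state[i] == "short") {
      "invalid"
    } else {
      classify_call(which(!is.na(values[i, ])), N)
    }
  }
  list(values = values, umi = umi, classification = classification)
}

#' Assign a feature from the mapping read
#'
#' RNA reads are matched by exact prefix (`min_read1_match` nt) against the
#' transcript 5' ends. ATAC reads must begin with the 19-nt Tn5 mosaic end
#' (at most 1 mismatch); the remainder is matched exactly against the toy
#' genome and located within the annotated accessible intervals.
#'
#' @param read1 Character vector of read-1 sequences.
#' @param reference A `bali_reference`.
#' @param modality `"RNA"` or `"ATAC"` (scalar or per-read vector).
#' @param config A `bali_decode_config`.
#' @return Data frame with columns `feature` (id or NA) and `position`
#'   (ATAC genome position of the insert, NA otherwise).
#' @export
assign_feature <- function(read1, reference, modality,
                           config = decode_config()) {
  n <- length(read1)
  if (length(modality) == 1L) modality <- rep(modality, n)
  feature <- rep(NA_character_, n)
  position <- rep(NA_integer_, n)
  k <- config$min_read1_match
  rna <- modality == "RNA"
  if (any(rna)) {
    pref <- substr(reference$transcripts, 1L, k)
    hit <- match(substr(read1[rna], 1L, k), pref)
    feature[rna] <- names(reference$transcripts)[hit]
  }
  if (any(!rna)) {
    me <- reference$mosaic_end
    meL <- nchar(me)
    i <- which(!rna)
    mm <- hamming_to(substr(read1[i], 1L, meL), me)
    has_me <- mm <= 1L
    i <- i[has_me]
    if (length(i)) {
      query <- substr(read1[i], meL + 1L, meL + k)
      g <- nchar(reference$genome)
      starts <- seq_len(g - k + 1L)
      kmers <- substring(reference$genome, starts, starts + k - 1L)
      posn <- match(query, kmers)
      acc <- reference$accessible
      iv <- findInterval(posn, acc$start)
      inside <- !is.na(posn) & iv >= 1L & posn <= acc$end[pmax(iv, 1L)]
      feature[i[inside]] <- acc$name[iv[inside]]
      position[i] <- posn
    }
  }
  data.frame(feature = feature, position = position)
}

#' Decode a simulated or real run
#'
#' Demultiplexes a FASTQ pair: calls index digits from read-2, classifies
#' barcode completeness with the parity automaton, maps complete codewords to
#' regions via the assignment, assigns features from read-1, collapses UMIs
#' per (region, feature), and tallies QC.
#'
#' @param r1,r2 Paths to the read-1 and read-2 FASTQ files.
#' @param dict A `bali_dictionary`.
#' @param assignment A `bali_assignment`.
#' @param reference A `bali_reference`.
#' @param config A `bali_decode_config`.
#' @return A `bali_decode` with elements `counts` (sparse region x feature
#'   UMI-deduplicated matrix), `qc` (reads_total, class fractions, per-region
#'   complete counts, partial spectrum, UMI dedup rate), `calls` (per-read
#'   table) and `fragments` (ATAC insert table, NULL for pure RNA runs).
#' @export
decode_run <- function(r1, r2, dict, assignment, reference,
                       config = decode_config()) {
  reads1 <- read_fastq(r1)
  reads2 <- read_fastq(r2)
  stopifnot(length(reads1) == length(reads2),
            all(names(reads1) == names(reads2)))
  n <- length(reads2)
  dec <- decode_reads2(unname(reads2), dict, config)
  digit_sets <- vapply(seq_len(n), function(i) {
    digitset_key(which(!is.na(dec$values[i, ])))
  }, character(1))
  cls <- dec$classification
  region <- rep(NA_integer_, n)
  complete <- cls == "complete"
  if (any(complete)) {
    keys <- apply(dec$values[complete, , drop = FALSE], 1L, paste,
                  collapse = "")
    amap <- setNames(assignment$labels, codeword_key(assignment$codewords))
    region[complete] <- unname(amap[keys])
  }
  unassigned_complete <- complete & is.na(region)
  # modality guess from read-1: mosaic-end prefix (<=1 mismatch) => ATAC
  me <- reference$mosaic_end
  mm_me <- hamming_to(substr(unname(reads1), 1L, nchar(me)), me)
  modality <- ifelse(mm_me <= 1L, "ATAC", "RNA")
  feat <- assign_feature(unname(reads1), reference, modality, config)
  calls <- data.frame(read = names(reads2), classification = cls,
                      digit_set = digit_sets, region = region,
                      modality = modality, feature = feat$feature,
                      position = feat$position, umi = dec$umi,
                      stringsAsFactors = FALSE)
  use <- complete & !is.na(region) & !is.na(feat$feature) & !is.na(dec$umi)
  counts <- umi_dedup_counts(region[use], feat$feature[use], dec$umi[use],
                             assignment$labels, config)
  frag <- NULL
  atac_use <- use & modality == "ATAC" & !is.na(feat$position)
  if (any(atac_use)) {
    frag <- data.frame(chrom = "toy_genome",
                       start = feat$position[atac_use] - 1L,
                       end = feat$position[atac_use] - 1L + 150L,
                       region = region[atac_use], umi = dec$umi[atac_use])
  }
  part <- table(digit_sets[cls == "reachable-partial"])
  qc <- list(
    reads_total = n,
    complete_fraction = mean(complete),
    complete_assigned = sum(complete & !is.na(region)),
    unassigned_complete = sum(unassigned_complete),
    partial_fraction = mean(cls == "reachable-partial"),
    invalid_fraction = mean(cls == "invalid"),
    ambiguous_fraction = mean(cls == "ambiguous"),
    per_region_complete = table(factor(region[complete],
                                       levels = assignment$labels)),
    partial_spectrum = setNames(as.integer(part), names(part)),
    umi_dedup_rate = if (sum(use)) sum(counts$matrix) / sum(use) else NA_real_)
  structure(list(counts = counts$matrix, qc = qc, calls = calls,
                 fragments = frag),
            class = "bali_decode")
}

# UMI-deduplicated sparse counts per (region, feature).
umi_dedup_counts <- function(region, feature, umi, all_labels, config) {
  if (!length(region)) {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(length(all_labels), 0L),
                              dimnames = list(as.character(all_labels), NULL))
    return(list(matrix = m))
  }
  grp <- paste(region, feature, sep = "\r")
  dedup <- integer(0)
  for (g in unique(grp)) {
    sel <- grp == g
    u <- umi[sel]
    k <- if (config$umi_collapse == "exact") {
      length(unique(u))
    } else {
      umi_cluster_count(u)
    }
    dedup[g] <- k
  }
  parts <- strsplit(names(dedup), "\r", fixed = TRUE)
  reg <- vapply(parts, `[[`, character(1), 1L)
  fea <- vapply(parts, `[[`, character(1), 2L)
  feats <- sort(unique(fea))
  m <- Matrix::sparseMatrix(
    i = match(reg, as.character(all_labels)),
    j = match(fea, feats), x = as.numeric(dedup),
    dims = c(length(all_labels), length(feats)),
    dimnames = list(as.character(all_labels), feats))
  list(matrix = m)
}

# Greedy directional single-mismatch UMI clustering: most frequent UMI seeds
# a cluster; UMIs within Hamming 1 of an existing seed are absorbed.
umi_cluster_count <- function(u) {
  tab <- sort(table(u), decreasing = TRUE)
  seeds <- character(0)
  for (x in names(tab)) {
    if (!length(seeds) ||
        all(vapply(seeds, function(s) str_hamming(s, x), integer(1)) > 1L)) {
      seeds <- c(seeds, x)
    }
  }
  length(seeds)
}

#' @export
print.bali_decode <- function(x, ...) {
  cat("Decoded run:", x$qc$reads_total, "read pairs\n")
  cat(sprintf("  complete %.1f%% | partial %.1f%% | invalid %.1f%% | ambiguous %.1f%%\n",
              100 * x$qc$complete_fraction, 100 * x$qc$partial_fraction,
              100 * x$qc$invalid_fraction, 100 * x$qc$ambiguous_fraction))
  cat("  count matrix:", nrow(x$counts), "regions x", ncol(x$counts),
      "features,", sum(x$counts), "UMIs\n")
  invisible(x)
}

#' Write decoder outputs to a directory
#'
#' Writes `counts.mtx` (MatrixMarket) with `regions.tsv` and `features.tsv`,
#' `qc.json`, the per-read `calls.tsv`, and `fragments.bed` (0-based
#' half-open) when ATAC fragments are present.
#'
#' @param res A `bali_decode`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_decode_outputs <- function(res, dir) {
  stopifnot(inherits(res, "bali_decode"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(res$counts, file.path(dir, "counts.mtx"))
  write.table(data.frame(region = rownames(res$counts)),
              file.path(dir, "regions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(feature = colnames(res$counts)),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  qc <- res$qc
  qc$per_region_complete <- as.list(setNames(as.integer(qc$per_region_complete),
                                             names(qc$per_region_complete)))
  qc$partial_spectrum <- as.list(qc$partial_spectrum)
  jsonlite::write_json(qc, file.path(dir, "qc.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  write.table(res$calls, file.path(dir, "calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(res$fragments)) {
    write.table(res$fragments, file.path(dir, "fragments.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
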