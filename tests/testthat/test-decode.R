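decode_fixture <- function(molecules = 300, efficiencies = 1, beta = 0,
                           err = 0, seed = 50, modality = "RNA",
                           shape = c(10, 20), pitch = 10) {
  g <- make_grid_regions(shape, pitch)
  a <- assign_barcodes(g, tiny_dict)
  plan <- compile_schedule(a, tiny_dict, g)
  cfg <- sim_config(efficiencies = efficiencies, background_uncaging = beta,
                    molecules_per_region = molecules, seq_error_rate = err,
                    modality = modality, seed = seed)
  run <- run_protocol(plan, cfg, tiny_ref)
  out <- emit_fastq(run, tempfile())
  truth <- read.table(out$truth, header = TRUE, sep = "\t",
                      colClasses = "character")
  list(plan = plan, assignment = a, out = out, truth = truth, cfg = cfg)
}

read2_for <- function(codeword, dict = tiny_dict, umi = strrep("T", 10),
                      digits = seq_along(codeword)) {
  body <- paste(vapply(seq_along(digits), function(i) {
    bali:::dict_unit(dict, digits[i], codeword[i])
  }, character(1)), collapse = "")
  bali:::pad_to(paste0(body, umi, dict$handle), 200L)
}

test_that("index calling round-trips codewords, tolerates one substitution, and parses partials", {
  r <- read2_for(c(0, 1, 0, 1))
  res <- call_indices(r, tiny_dict)
  expect_equal(res$calls$digit, 1:4)
  expect_equal(res$calls$value, c(0L, 1L, 0L, 1L))
  expect_equal(res$classification, "complete")
  expect_equal(res$umi, strrep("T", 10))

  # one substitution inside a core still calls (Hamming 1 < min_hamming 3)
  mut <- r
  substr(mut, 10, 10) <- ifelse(substr(r, 10, 10) == "A", "G", "A")
  res_mut <- call_indices(mut, tiny_dict)
  expect_equal(res_mut$calls, res$calls)

  # missing digit 1: parse starts at the digit-3 unit
  partial <- read2_for(c(0, 1), digits = c(3, 4))
  res_p <- call_indices(partial, tiny_dict)
  expect_equal(res_p$digit_set, c(3L, 4L))
  expect_equal(res_p$classification, "reachable-partial")

  # too short for one unit + UMI
  expect_equal(call_indices("ACGT", tiny_dict)$classification, "invalid")
})

test_that("classification follows the parity automaton", {
  expect_equal(classify_call(1:4, 4), "complete")
  expect_equal(classify_call(c(1, 4), 4), "reachable-partial")
  expect_equal(classify_call(c(3, 4), tiny_dict), "reachable-partial")
  expect_equal(classify_call(c(2, 4), 4), "invalid")
  expect_equal(classify_call(c(1, 2), 4), "invalid")  # unamplifiable
  expect_equal(classify_call(integer(0), 4), "invalid")
  # agreement with the reachable/observable oracles over all subsets of 4
  obs <- oracle_reachable_sets(4)
  for (i in 0:15) {
    members <- which(bitwAnd(i, 2^(0:3)) > 0)
    key <- paste(members, collapse = ",")
    expected <- if (length(members) == 4) "complete"
      else if (key %in% obs && 4 %in% members) "reachable-partial"
      else "invalid"
    expect_equal(classify_call(members, 4), expected, info = key)
  }
})

test_that("feature assignment matches transcripts and mosaic-end ATAC reads", {
  rna_read <- substr(tiny_ref$transcripts[["tx03"]], 1, 100)
  res <- assign_feature(rna_read, tiny_ref, "RNA")
  expect_equal(res$feature, "tx03")

  acc <- tiny_ref$accessible[2, ]
  insert <- substr(tiny_ref$genome, acc$start, acc$start + 80)
  atac <- substr(paste0(tiny_ref$mosaic_end, insert), 1, 100)
  res2 <- assign_feature(atac, tiny_ref, "ATAC")
  expect_equal(res2$feature, acc$name)
  expect_equal(res2$position, acc$start)

  # one substitution inside the mosaic end is tolerated
  atac_mut <- atac
  substr(atac_mut, 3, 3) <- ifelse(substr(atac, 3, 3) == "A", "C", "A")
  expect_equal(assign_feature(atac_mut, tiny_ref, "ATAC")$feature, acc$name)

  # no mosaic end -> unassigned
  expect_true(is.na(assign_feature(insert, tiny_ref, "ATAC")$feature))
})

test_that("a noiseless run decodes to 100% complete with perfect region and feature recovery", {
  fx <- decode_fixture()
  dec <- decode_run(fx$out$r1, fx$out$r2, tiny_dict, fx$assignment, tiny_ref)
  expect_equal(dec$qc$reads_total, 600L)
  expect_equal(dec$qc$complete_fraction, 1)
  expect_equal(dec$qc$invalid_fraction, 0)
  ord <- match(fx$truth$read, dec$calls$read)
  expect_equal(as.character(dec$calls$region[ord]), fx$truth$region)
  expect_equal(dec$calls$feature[ord], fx$truth$feature)
  expect_equal(dec$calls$umi[ord], fx$truth$umi)
  expect_equal(sum(dec$counts), 600)  # UMIs all distinct at n = 600
})

test_that("ATAC runs decode to fragments and intervals", {
  fx <- decode_fixture(molecules = 200, modality = "ATAC")
  dec <- decode_run(fx$out$r1, fx$out$r2, tiny_dict, fx$assignment, tiny_ref)
  expect_equal(dec$qc$complete_fraction, 1)
  ord <- match(fx$truth$read, dec$calls$read)
  expect_equal(dec$calls$feature[ord], fx$truth$feature)
  expect_false(is.null(dec$fragments))
  expect_true(all(dec$fragments$start >= 0))
})

test_that("depressed first-cycle efficiency makes {3,4} the dominant incomplete set", {
  fx <- decode_fixture(molecules = 3000, efficiencies = c(0.5, 0.95, 0.9, 0.9),
                       seed = 51)
  dec <- decode_run(fx$out$r1, fx$out$r2, tiny_dict, fx$assignment, tiny_ref)
  sp <- dec$qc$partial_spectrum
  expect_equal(names(which.max(sp)), "3,4")
  # counts conservation across classes
  n <- dec$qc$reads_total
  expect_equal(sum(dec$qc$complete_fraction * n, dec$qc$partial_fraction * n,
                   dec$qc$invalid_fraction * n, dec$qc$ambiguous_fraction * n),
               n)
  ratio <- infer_first_vs_second_failure_ratio(sp)
  expected <- (0.5 * 0.9) / (0.5 * 0.05)  # = 18 from the path probabilities
  expect_lt(abs(ratio - expected), 4.5)
})

test_that("UMI deduplication collapses duplicate molecules", {
  # two reads with identical (region, feature, UMI) count once
  cw <- c(0L, 0L, 0L, 0L)
  r2 <- rep(read2_for(cw, umi = strrep("G", 10)), 2)
  r1 <- rep(substr(tiny_ref$transcripts[["tx01"]], 1, 100), 2)
  d <- tempfile(); dir.create(d)
  bali:::write_fastq(setNames(r1, c("a", "b")), file.path(d, "r1.fq"))
  bali:::write_fastq(setNames(r2, c("a", "b")), file.path(d, "r2.fq"))
  g <- make_grid_regions(c(10, 20), 10)
  a <- assign_barcodes(g, tiny_dict)
  dec <- decode_run(file.path(d, "r1.fq"), file.path(d, "r2.fq"),
                    tiny_dict, a, tiny_ref)
  expect_equal(dec$qc$reads_total, 2L)
  expect_equal(sum(dec$counts), 1)
  expect_equal(dec$qc$umi_dedup_rate, 0.5)
  # single-mismatch collapse merges near-identical UMIs
  r2b <- c(read2_for(cw, umi = strrep("G", 10)),
           read2_for(cw, umi = paste0(strrep("G", 9), "T")))
  bali:::write_fastq(setNames(r2b, c("a", "b")), file.path(d, "r2b.fq"))
  dec2 <- decode_run(file.path(d, "r1.fq"), file.path(d, "r2b.fq"),
                     tiny_dict, a, tiny_ref,
                     decode_config(umi_collapse = "single-mismatch"))
  expect_equal(sum(dec2$counts), 1)
  dec3 <- decode_run(file.path(d, "r1.fq"), file.path(d, "r2b.fq"),
                     tiny_dict, a, tiny_ref)
  expect_equal(sum(dec3$counts), 2)
})

test_that("failure-ratio helper divides counts and applies the efficiency correction", {
  expect_equal(infer_first_vs_second_failure_ratio(c("3,4" = 300, "1,4" = 20)),
               15)
  expect_equal(infer_first_vs_second_failure_ratio(
    c("3,4" = 300, "1,4" = 20), p_estimates = c(0.5, 0.9, 0.75, 0.9)),
    15 * 0.5 / 0.75)
  expect_warning(
    r <- infer_first_vs_second_failure_ratio(c("3,4" = 10)), "undefined")
  expect_true(is.na(r))
})

test_that("with 0.1% sequencing error and Hamming-3 cores, no read is mis-assigned", {
  fx <- decode_fixture(molecules = 50000, err = 0.001, seed = 52)
  dec <- decode_run(fx$out$r1, fx$out$r2, tiny_dict, fx$assignment, tiny_ref)
  expect_gte(dec$qc$reads_total, 100000L)
  ord <- match(fx$truth$read, dec$calls$read)
  assigned <- !is.na(dec$calls$region[ord])
  expect_equal(sum(as.character(dec$calls$region[ord][assigned]) !=
                     fx$truth$region[assigned]), 0L)
})

test_that("decoder outputs write as MTX + TSV + JSON + BED", {
  fx <- decode_fixture(molecules = 50, modality = "ATAC")
  dec <- decode_run(fx$out$r1, fx$out$r2, tiny_dict, fx$assignment, tiny_ref)
  d <- tempfile()
  write_decode_outputs(dec, d)
  expect_true(all(file.exists(file.path(d, c("counts.mtx", "regions.tsv",
                                             "features.tsv", "qc.json",
                                             "calls.tsv", "fragments.bed")))))
  m <- Matrix::readMM(file.path(d, "counts.mtx"))
  expect_equal(sum(m), sum(dec$counts))
})
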