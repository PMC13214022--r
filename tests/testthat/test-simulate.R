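# Shared fixture: a 2-region, 4-digit plan over the tiny dictionary.
sim_fixture <- function(molecules = 500, efficiencies = 1, beta = 0,
                        err = 0, seed = 10, modality = "RNA") {
  g <- make_grid_regions(c(10, 20), 10)
  a <- assign_barcodes(g, tiny_dict)
  plan <- compile_schedule(a, tiny_dict, g)
  cfg <- sim_config(efficiencies = efficiencies, background_uncaging = beta,
                    molecules_per_region = molecules, seq_error_rate = err,
                    modality = modality, seed = seed)
  list(plan = plan, cfg = cfg, map = g, assignment = a)
}

test_that("populations initialise per region, caged and digit-free, deterministically", {
  fx <- sim_fixture(molecules = 1000)
  pop <- init_molecules(fx$plan$region_map, fx$cfg, tiny_ref)
  expect_equal(pop$n, 2000L)
  expect_equal(as.integer(table(pop$region)), c(1000L, 1000L))
  expect_true(all(pop$caged))
  expect_true(all(pop$last == 0L))
  pop2 <- init_molecules(fx$plan$region_map, fx$cfg, tiny_ref)
  expect_identical(pop, pop2)
  empty_ref <- tiny_ref
  empty_ref$transcripts <- character(0)
  expect_error(init_molecules(fx$plan$region_map, fx$cfg, empty_ref),
               "no transcripts")
})

test_that("transcript abundance weights shape the sampled features", {
  fx <- sim_fixture(molecules = 4000)
  cfg <- fx$cfg
  cfg$abundance <- list("1" = c(tx01 = 0.9, tx02 = 0.1))
  pop <- init_molecules(fx$plan$region_map, cfg, tiny_ref)
  frac <- mean(pop$feature[pop$region == 1L] == "tx01")
  se <- sqrt(0.9 * 0.1 / 4000)
  expect_lt(abs(frac - 0.9), 3 * se)
  # other region untouched by the region-specific table: uniform over 6
  expect_gt(length(unique(pop$feature[pop$region == 2L])), 3L)
})

test_that("a perfect protocol writes every region's complete codeword", {
  fx <- sim_fixture(molecules = 300)
  run <- run_protocol(fx$plan, fx$cfg, tiny_ref)
  pop <- run$population
  expect_equal(pop$n, 600L)  # conservation
  expect_true(all(!is.na(pop$values)))
  for (r in 1:2) {
    cw <- fx$assignment$codewords[fx$assignment$labels == r, ]
    rows <- pop$values[pop$region == r, , drop = FALSE]
    expect_true(all(t(rows) == cw))
  }
  expect_true(all(run$spectrum$digit_set == "1,2,3,4"))
})

test_that("without background uncaging, non-illuminated molecules are never modified", {
  fx <- sim_fixture(molecules = 200)
  pop <- init_molecules(fx$plan$region_map, fx$cfg, tiny_ref)
  pop <- apply_step(pop, fx$plan, 1, fx$cfg)  # digit 1, value 0: region 1 only
  in_step <- fx$plan$regions_per_step[[1]]
  out <- !(pop$region %in% in_step)
  expect_true(all(is.na(pop$values[out, ])))
  expect_true(all(pop$caged[out]))
  expect_true(all(pop$values[!out, 1] == 0L))
})

test_that("digit-set frequencies follow the parity-automaton path probabilities", {
  p <- 0.8
  fx <- sim_fixture(molecules = 20000, efficiencies = p, seed = 21)
  run <- run_protocol(fx$plan, fx$cfg, tiny_ref)
  ds <- population_spectrum(run$population)
  tot <- sum(ds$count)
  obs34 <- sum(ds$count[ds$digit_set == "3,4"]) / tot
  expected <- (1 - p) * p * p  # fail 1, blocked 2, ligate 3 and 4
  se <- sqrt(expected * (1 - expected) / tot)
  expect_lt(abs(obs34 - expected), 4 * se)
  # every observed digit set is chemically reachable
  expect_true(all(vapply(ds$digit_set, function(k) {
    is_reachable(if (k == "") integer(0) else
      as.integer(strsplit(k, ",")[[1]]), 4)
  }, logical(1))))
})

test_that("digit sets stay reachable even with background uncaging", {
  fx <- sim_fixture(molecules = 5000, efficiencies = 0.85, beta = 0.05,
                    seed = 22)
  run <- run_protocol(fx$plan, fx$cfg, tiny_ref)
  ds <- population_spectrum(run$population)
  expect_true(all(vapply(ds$digit_set, function(k) {
    is_reachable(if (k == "") integer(0) else
      as.integer(strsplit(k, ",")[[1]]), 4)
  }, logical(1))))
})

test_that("the extension ladder converges to the product of per-cycle efficiencies", {
  lad <- simulate_extension_ladder(rep(1, 5), molecules = 2000, seed = 1)
  expect_equal(unname(lad[["5"]]), 1)
  lad2 <- simulate_extension_ladder(0.5, molecules = 1e5, seed = 2, digits = 1)
  expect_lt(abs(lad2[["1"]] - 0.5), 4 * sqrt(0.25 / 1e5))
  p <- c(0.814, rep(0.948, 6))
  lad3 <- simulate_extension_ladder(p, molecules = 1e5, seed = 3)
  expected <- prod(p)  # 0.591
  expect_lt(abs(lad3[["7"]] - expected), 4 * sqrt(expected * (1 - expected) / 1e5))
})

test_that("only terminal-digit molecules emit reads, and reads reconstruct the barcode", {
  fx <- sim_fixture(molecules = 200)
  run <- run_protocol(fx$plan, fx$cfg, tiny_ref)
  out <- emit_fastq(run, tempfile())
  expect_equal(out$n_reads, 400L)  # p = 1: every molecule emits
  r2 <- bali:::read_fastq(out$r2)
  expect_true(all(nchar(r2) == 200L))
  # error-free read-2 starts with the exact unit concatenation per region
  truth <- read.table(out$truth, header = TRUE, sep = "\t",
                      colClasses = "character")
  for (r in c("1", "2")) {
    cw <- fx$assignment$codewords[fx$assignment$labels == as.integer(r), ]
    units <- paste(vapply(1:4, function(n) {
      bali:::dict_unit(tiny_dict, n, cw[n])
    }, character(1)), collapse = "")
    sel <- truth$region == r
    expect_true(all(startsWith(r2[truth$read[sel]], units)))
    # ...then the UMI and the shared handle
    expect_true(all(substr(r2[truth$read[sel]],
                           nchar(units) + 1L, nchar(units) + 10L) ==
                    truth$umi[sel]))
  }
})

test_that("a failed first ligation forces the {3,4} partial barcode", {
  fx <- sim_fixture(molecules = 300, efficiencies = c(0, 1, 1, 1), seed = 30)
  run <- run_protocol(fx$plan, fx$cfg, tiny_ref)
  out <- emit_fastq(run, tempfile())
  truth <- read.table(out$truth, header = TRUE, sep = "\t",
                      colClasses = "character")
  expect_gt(nrow(truth), 0L)
  expect_true(all(truth$digit_set == "3,4"))
})

test_that("FASTQ emission is byte-identical under a fixed seed", {
  fx <- sim_fixture(molecules = 100, efficiencies = 0.9, beta = 0.01,
                    err = 0.002, seed = 31)
  d1 <- tempfile(); d2 <- tempfile()
  emit_fastq(run_protocol(fx$plan, fx$cfg, tiny_ref), d1)
  emit_fastq(run_protocol(fx$plan, fx$cfg, tiny_ref), d2)
  for (f in c("R1.fastq", "R2.fastq", "truth.tsv")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     info = f)
  }
})

test_that("emitted digit sets are always observable", {
  fx <- sim_fixture(molecules = 2000, efficiencies = 0.7, seed = 32)
  run <- run_protocol(fx$plan, fx$cfg, tiny_ref)
  out <- emit_fastq(run, tempfile())
  truth <- read.table(out$truth, header = TRUE, sep = "\t",
                      colClasses = "character")
  expect_lte(nrow(truth), run$population$n)
  obs <- vapply(observable_digit_sets(4),
                function(s) paste(s, collapse = ","), character(1))
  expect_true(all(truth$digit_set %in% obs))
})
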