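# bali

Design, simulation and decoding of light-directed combinatorial spatial
barcodes.

Spatial omics methods that write DNA barcodes onto biomolecules with
patterned light can profile user-defined tissue regions — from a handful of
anatomical structures to millions of spots — with a single sequencing
library. A photocaged ligation root is installed on every target molecule
(by reverse transcription for mRNA, Tn5 tagmentation for open chromatin);
serial cycles of patterned UV illumination and bulk ligation then append DNA
"index" units digit by digit, building a combinatorial barcode of `N` digits
with `i` values each, for a capacity of

```
i^N   (base 2, 4 digits -> 16 regions; base 4, 10 digits -> ~1 million)
```

Each index is flanked by alternating 6- and 7-nt ligation overhangs, so a
failed cycle leaves the acceptor parity unchanged and only parity-legal
partial barcodes can form; only molecules that receive the terminal index
(which carries the UMI and PCR handle) are sequenced. The complete-barcode
yield is the product of the per-cycle ligation efficiencies, `p^N` for a
uniform efficiency.

This package is for people building or analysing such experiments. It
provides:

* **Dictionary design** — `build_dictionary()`, `validate_dictionary()`,
  GC-based overhang ranking, Hamming-separated index cores, JSON I/O.
* **Protocol compilation** — label images or grids to region maps
  (`regions_from_label_image()`, `make_grid_regions()`), injective barcode
  assignment (`assign_barcodes()`), per-step photomask schedules
  (`compile_schedule()`, `render_masks()`, `export_protocol()`), duration
  estimates and FWHM resolution QC (`measure_fwhm()`).
* **Chemistry simulation** — a molecule-level stochastic model of
  uncaging/ligation (`run_protocol()`) with background-uncaging chimeras,
  emitting truth-tracked paired FASTQ (`emit_fastq()`).
* **Decoding** — parity-aware greedy barcode parsing, completeness
  classification, feature assignment, UMI deduplication and QC
  (`decode_run()`), with MatrixMarket/BED/JSON outputs.
* **Efficiency inference** — closed-form digit-set distributions
  (`digit_set_probabilities()`), yield forecasts (`forecast_table()`), and
  maximum-likelihood recovery of per-cycle efficiencies from barcode
  spectra (`fit_per_cycle()`).

## Worked example

Simulate a 4-region, 4-digit (base 2) experiment with a depressed
first-cycle efficiency, decode it, and recover the efficiencies from the
barcode spectrum alone:

```r
library(bali)

dict <- build_dictionary(base = 2, digits = 4, seed = 1)
dict
#> Barcode dictionary: base 2 x 4 digits (capacity 16)
#>   overhangs: odd-acceptor AAATTA | even-acceptor AAATCAA
#>   cores: 8 x 10 nt, min pairwise Hamming 3
#>   terminal digit adds 10 nt UMI + 20 nt handle

map <- make_grid_regions(c(40, 40), pitch = 20)   # 4 square regions
assignment <- assign_barcodes(map, dict)
plan <- compile_schedule(assignment, dict, map)
plan
#> Illumination protocol: 8 steps (base 2 x 4 digits), 4 regions
#>   estimated duration: 792 minutes

ref <- make_toy_reference(seed = 1)
cfg <- sim_config(efficiencies = c(0.6, 0.95, 0.95, 0.95),
                  background_uncaging = 0, molecules_per_region = 5000,
                  seq_error_rate = 0.001, seed = 1)
run <- run_protocol(plan, cfg, ref)
run
#> Simulated run: 20000 molecules, complete-barcode fraction 0.508

fq <- emit_fastq(run, "example_run")
dec <- decode_run(fq$r1, fq$r2, dict, assignment, ref)
dec
#> Decoded run: 18065 read pairs
#>   complete 56.3% | partial 43.7% | invalid 0.0% | ambiguous 0.0%
#>   count matrix: 4 regions x 8 features, 9844 UMIs

fit <- fit_per_cycle(c(dec$qc$partial_spectrum,
                       "1,2,3,4" = dec$qc$complete_assigned),
                     digits = 4, constraint = "shared-bulk")
summary(fit)
#> Per-cycle ligation efficiency fit (shared-bulk, N = 4)
#>
#> Coefficients:
#>        estimate std.error
#> p1       0.5957    0.0037
#> p_bulk   0.9466    0.0020
#>
#> Observable spectrum (fractions):
#>  digit_set observed fitted
#>        1,4   0.0336 0.0336
#>        3,4   0.4036 0.4036
#>    1,2,3,4   0.5629 0.5629
#>
#> Implied complete-barcode yield: 0.5053
```

Reading the output: only 18,065 of the 20,000 molecules carry the terminal
digit and emit reads. Among those, 56.3% carry the complete barcode — the
fraction is higher than the population's 50.8% because sequencing conditions
on observability. The dominant incomplete barcode is digits 3-4 (first
ligation failed), the rarer one digits 1-4 (second failed), and the fit
recovers the generating efficiencies (0.6, 0.95) from the spectrum to two
decimals. The count matrix holds UMI-deduplicated transcript counts per
region.

A thin command-line wrapper over the same functions ships in
`inst/cli/bali.R` with `schedule`, `simulate`, `decode` and `estimate`
subcommands.

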