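---
title: "Light-directed combinatorial spatial barcoding: model, simulator and decoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Light-directed combinatorial spatial barcoding: model, simulator and decoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bali)
```

## The encoding scheme

Light-directed combinatorial barcoding writes a spatial barcode directly onto
biomolecules in a tissue section. A ligation root with a photocaged 5'
phosphate is installed on every target molecule (by reverse transcription for
mRNA, by Tn5 tagmentation for accessible chromatin). A barcode of `N` digits,
each with `i` possible values (the base), is then assembled by serial cycles:
for each digit `n` and value `v`, all regions assigned value `v` at digit `n`
are illuminated with patterned UV light, uncaging their molecules, and a DNA
index encoding `(n, v)` is ligated in bulk. The number of addressable regions
is `i^N` — 16 regions from 8 indexes (base 2, 4 digits), a million from 40
(base 4, 10 digits).

Each index is a staggered double-stranded unit flanked by two orthogonal
single-stranded overhangs, one 6 nt and one 7 nt, used in strict alternation:
digit 1 ligates onto the root's odd-acceptor overhang and regenerates the
even-acceptor (again photocaged), digit 2 the reverse, and so on. Overhang
candidates are ranked by GC content (T4 DNA ligase activity on 6-7 nt
overhangs falls with GC), and a pair is rejected when one overhang's reverse
complement matches the other within one mismatch, which would allow
concatemer formation. Terminal (digit `N`) indexes additionally carry a
unique molecular identifier (UMI) and the PCR handle — a molecule that never
receives the terminal digit is not amplifiable and never appears in
sequencing.

## The parity automaton and partial barcodes

Because the overhangs alternate, a failed ligation has a characteristic
signature. After ligating digit `j` the exposed acceptor expects the parity
of `j + 1`; if a ligation fails, the acceptor parity is unchanged and the
next digit that can ligate is `j + 2` (same parity, later cycle). The
chemically reachable digit sets are therefore exactly the strictly increasing
sequences that start with an odd digit and alternate parity:

```{r}
enumerate_reachable_digit_sets(4)
```

Of the `2^4` conceivable subsets only these 8 are reachable, and only the
three containing digit 4 — the full barcode, `{1,4}` and `{3,4}` — are
observable in sequencing:

```{r}
observable_digit_sets(4)
```

This is why, in a 4-digit experiment, the only abundant incomplete barcodes
are digits 3-4 (first ligation failed) and digits 1-4 (second failed), and
why their count ratio `((1 - p1) p3) / (p1 (1 - p2))` measures the relative
failure rates of the first two cycles
(`infer_first_vs_second_failure_ratio()`).

## Efficiency model

With per-cycle ligation success probabilities `p_1..p_N`, the probability of
every reachable digit set follows by running the automaton
(`digit_set_probabilities()`); the complete-barcode yield is the product
`prod(p_k)`, i.e. `p^N` for a uniform efficiency — exponential decay in the
barcode length:

```{r}
p <- 0.648^(1 / 3)  # per-cycle basis from a 64.8% cumulative over 3 cycles
forecast_table(p, c(3, 5, 8, 10))
```

A per-cycle efficiency in the mid-80s% therefore supports a thousand regions
(5 digits, base 4) at roughly 48% complete barcodes and a million (10
digits) at roughly 23%.

`fit_per_cycle()` inverts this model: it maximises the multinomial
likelihood of an observed spectrum of digit-set counts, with category
probabilities conditioned on observability (sets containing digit `N`),
because the unamplified molecules are never counted. Conditioning removes
the need for a latent total-molecule parameter. Three constraints are
offered. `scalar` fits one shared `p`; `shared-bulk` fits a free first cycle
plus one bulk value (the first cycle is systematically lower in practice,
plausibly a surface effect); `free` fits all `p_k` but is refused when the
parameter count exceeds the spectrum's degrees of freedom — for `N = 4`
there are only 3 observable categories, so at most 2 free parameters are
identifiable. Optimisation is on the logit scale (unconstrained), from 5
deterministic starting values, with standard errors from the observed
information delta-transformed back to probabilities. Estimates within 1e-6
of 0 or 1, or fits to a single-category spectrum, are flagged as boundary
estimates and reported without standard errors.

```{r}
sp <- simulate_spectrum(efficiency_model(c(0.6, 0.95, 0.95, 0.95)), 1e5,
                        seed = 1)
summary(fit_per_cycle(sp, digits = 4, constraint = "shared-bulk"))
```

## From region map to protocol

`regions_from_label_image()` turns an integer label raster (0 = background)
into a region table, dropping regions below a minimum area;
`make_grid_regions()` builds regular grids. `assign_barcodes()` maps regions
to codewords injectively — sequentially in mixed-radix order (digit 1 is the
least-significant position), as a seeded random sample, or greedily
maximising the minimum pairwise Hamming distance (deterministic,
lexicographic tie-breaks). `compile_schedule()` emits one step per
(digit, value) in digit-major, value-minor order — `base * digits` steps in
total, so 20 steps address 1,024 regions at base 2 — and `render_masks()`
materialises the photomasks. Within each digit the value masks partition the
assigned pixels: every region is illuminated exactly once per digit, and
background never. The default durations (90 min ligation + 9 min fluidics
and imaging overhead per step) put a 20-step protocol at 33 h; both numbers
are arguments of `compile_schedule()`.

The within-digit value order is not dictated by the chemistry; ascending
value order is imposed for determinism. `measure_fwhm()` supports resolution
QC: it returns the full width at half maximum of a line profile after
subtracting a baseline estimated as the median of the outer 10% of samples,
with linear interpolation at the half-maximum crossings.

## The simulator

`run_protocol()` is a stochastic forward model at molecule resolution. Each
molecule carries its region, a feature (a transcript for RNA molecules, an
accessible-interval fragment for ATAC), the set of ligated digit values, the
exposed acceptor parity, and a caged flag. At every step a molecule is
*eligible* if its region is illuminated or a background uncaging event
occurs (probability `beta` per molecule per step, default 0.018 — the
published background figure is an end-point image ratio, and a per-step rate
is the simplest generative mechanism consistent with it; the two are not
asserted to be numerically identical). Eligible caged molecules are uncaged;
eligible uncaged molecules whose acceptor parity matches the step's digit
ligate with probability `p_digit`, recording the *step's* value (so
background-uncaged molecules can acquire wrong-value digits, the chimera
mechanism), flipping parity and re-caging. Ligation is gated on per-step
eligibility, so with `beta = 0` a molecule outside the mask is never touched
and the complete-barcode fraction converges exactly to `prod(p_k)`.

`emit_fastq()` writes the paired reads for every amplifiable molecule:
read-1 (100 nt) is the mapping read — the transcript 5' end, or the 19-nt
Tn5 mosaic end followed by the genomic insert; read-2 (200 nt) is the
barcode read — the ligated units (incoming overhang + 10-nt core) in
ligation order, then the 10-nt UMI and 20-nt handle, padded with A.
Substitution errors are applied at the configured rate (no indels: the
ligation products have fixed length structure). Everything is deterministic
under the configuration seed, down to byte-identical FASTQ.

Default generator settings — 1,000 molecules per region, base-2 dictionaries
with 10-nt cores at minimum pairwise Hamming distance 3, GC 30-70%,
homopolymers capped at 3, efficiency 0.86, background 0.018, sequencing
error 0.001 — are chosen to mirror a realistic experiment of this kind. The
toy references are random sequences; the simulator reproduces the barcode
chemistry and read structure, not transcriptome complexity, alignment
ambiguity, PCR bias or optical effects, so passing round-trip tests
demonstrates correctness of the encoding/decoding logic rather than
performance on real libraries.

## The decoder

`decode_run()` parses read-2 greedily left to right. At each position the
automaton restricts the candidates to digits beyond the last call with the
correct acceptor parity; since all such units share one overhang, calls are
decided by the cores, which are generated at pairwise Hamming distance >= 3
across the whole dictionary. A unique unit within the mismatch tolerance
(default 1) is accepted; two within tolerance classify the read as
`ambiguous` (never guessed); none ends the barcode. The resulting digit set
is classified `complete`, `reachable-partial` (observable but incomplete) or
`invalid` (chemically unreachable — an error signature). Complete codewords
map to regions through the assignment; valid codewords absent from the
assignment are tallied as unassigned rather than dropped. Features are
assigned by exact 30-nt prefix match for RNA and by mosaic-end detection
(<= 1 mismatch) plus exact genomic match for ATAC — real-genome alignment is
deliberately out of scope and delegated to standard aligners. UMIs are
collapsed per (region, feature), exactly by default or by greedy
single-mismatch clustering. Outputs are a sparse region-by-feature count
matrix (MatrixMarket), an ATAC fragment table (BED), per-read calls and a QC
report whose classes partition the read total.

## Numerical and design choices

* Digit 1 is odd and ligates the root's odd acceptor; this convention fixes
  the automaton and is shared by simulator, decoder and closed forms.
* Dictionary generation is rejection sampling under the core constraints;
  infeasible requests (e.g. Hamming 3 at core length 1) fail fast naming the
  binding constraint.
* The decoder tolerance must satisfy `max_mismatches < min_hamming`; with
  the defaults (1 < 3) a single substitution can never flip a call, which is
  why the mis-assignment rate at a 0.1% error rate is zero in the test
  suite's 100,000-read experiment.
* The per-cycle basis for yield forecasts is genuinely uncertain at the
  second decimal: a cumulative 64.8% over three cycles gives
  `p = 0.648^(1/3) = 0.865` (yields 48.5% / 23.5% at 5 / 10 digits) while a
  flat 86% gives 47.0% / 22.1%. The package defaults to the
  cumulative-derived basis and `forecast_table()` accepts any scalar, so
  both ends of the bracket are one call away.
* Simulation sizes in the tests (1e5 molecules for Monte-Carlo convergence
  and likelihood recovery, 2 x 50,000 molecules for the error-robustness
  round trip) were chosen so that 4-sigma binomial checks are sharp at the
  asserted tolerances.

## Known limitations

The simulator models neither PCR duplication (beyond UMI sampling) nor
ligase kinetics, thermodynamic annealing or reagent diffusion; overhang
cross-reactivity is a sequence heuristic, not a hybridisation model. The
efficiency likelihood ignores sequencing-error-induced misclassification
(negligible at default settings, by the decoder guarantee above). Masks are
single-field rasters; multi-field stitching is out of scope.
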