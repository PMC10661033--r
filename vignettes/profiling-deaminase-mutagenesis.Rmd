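---
title: "Profiling targeted deaminase mutagenesis from amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling targeted deaminase mutagenesis from amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprofile)
library(dplyr)
```

## The problem

A diversifying base editor (DBE) tethers a cytidine deaminase — typically an
engineered AID variant — to catalytically dead Cas9 through MS2 aptamers in
the guide scaffold, so that a single guide RNA concentrates point mutations
in a window of roughly ±50 bp around its PAM. Used in yeast, such editors
generate *in situ* mutant libraries for directed evolution. Quantifying one
is a sequencing problem: amplify the targeted locus, sequence it deeply
(paired-end amplicon sequencing), and reduce the reads to per-position
substitution frequencies, a background-subtracted window average, a
per-generation mutation rate, a substitution spectrum, and per-read
mutation multiplicities.

`crisprofile` implements that reduction end to end, together with a forward
simulator of the editing process so that every stage can be validated
against a generative truth without any external dataset.

## The generative model

Each site $i$ of the amplicon receives, per generation, a substitution with
probability

$$ q_i \;=\; r \cdot w(d_i) \cdot m(\mathrm{context}_i) \cdot s(\mathrm{base}_i), $$

clamped to $[0,1]$, where

* $r$ is the base per-site per-generation substitution probability
  (dimensionless; default $2.13\times10^{-4}$, a realistic rate for an
  enhanced AID-based editor);
* $w(d)$ weights the PAM-relative distance $d$ (0 at the PAM 3′ end, signed
  along the protospacer strand). Shapes: `uniform` ($w=1$ for $|d|\le W$,
  else 0; default, $W = 50$ bp), `triangular`, `gaussian`. When several
  guides overlap a site the largest weight wins;
* $m$ is a motif multiplier reflecting AID's preference for cytidines in
  WRCY motifs (W=A/T, R=A/G, Y=C/T), strongest at the palindromic AGCT.
  Context is classified on the strand where the cytosine resides — for a
  reference G the 4-mer is read from the template strand. Classes:
  `agct`, `wrcy` (non-AGCT), `other`;
* $s$ distinguishes C:G pairs (the deaminase's substrate, default 1) from
  the A:T background (default 1 in the neutral configuration; calibrated
  down to reproduce a measured A/T share, see below).

Over $g$ generations (fractional allowed) the cumulative mutated fraction
is the closed form

$$ p_i = 1 - (1 - q_i)^g, $$

and each genome carries at most one substitution per site (no
back-mutation). We chose the analytic compounding over discrete
per-generation Bernoulli rounds because realistic passage counts are
non-integer (optical-density records give, e.g., 20.5 doublings) and only
cumulative frequencies are observable. Alternative bases are drawn from a
row-stochastic outcome spectrum; the default C row is C→G 0.5, C→T 0.35,
C→A 0.15 — a deliberate placeholder encoding the C→G preference of
DBE-style editors with uracil-glycosylase-driven repair, not a measured
distribution — with the G row mirrored by complement and uniform A/T rows
for background events. Indels are modelled as single-base deletions at a
per-site per-genome rate (default 0; observed indel rates in this kind of
data are ~$10^{-5}$ and below).

With the default uniform window the model places no signal outside the
guide windows at all; the A:T background term therefore acts within the
window, which is also where the spectrum and its A/T share are measured.

### What the simulator does and does not emulate

Reads emulate end-anchored PE250 amplicon sequencing: read 1 covers the
amplicon 5′ end, read 2 the 3′ end reverse-complemented, with constant Q30
qualities and substitution-type sequencing errors injected at a configurable
rate (written at Q15). Not modelled: PCR bias and chimeras, duplicates,
quality degradation along the read, selection or fitness effects in the
population, multi-contig references. Passing tests on simulated data
therefore validate the *arithmetic* of the pipeline — counting, coordinate
transforms, normalization — not its robustness to those real-data artifacts.

Seeding is split by phase: the configuration seed drives genome draws only,
and read sampling takes its own seed, so changing the number of reads never
perturbs the simulated population.

## The measurement chain

1. **Merge** (`merge_read_pairs()`): exhaustive overlap scan; among overlaps
   of length ≥ `min_overlap` (20 bp) with mismatch fraction ≤
   `max_mismatch_frac` (0.1), the one maximizing matching bases wins, ties
   to the longer overlap. Consensus takes the higher-quality base
   (read 1 on ties); consensus quality is the maximum where mates agree and
   the minimum where they disagree. Unmerged pairs are counted and dropped,
   as merged-only analysis is the norm for amplicon data.
2. **Align** (`align_reads()`): optimal glocal alignment (read global,
   reference local) with affine gaps, scoring match +1, mismatch −1, gap
   open −4, gap extend −1 — appropriate for short amplicons with few
   expected edits. Reads under 80% identity are flagged unaligned (a value,
   not an error). Equal-length reads with ≤ 3 gap-free mismatches are
   resolved without the dynamic program; this shortcut is provably optimal
   under the default scoring because any gapped alternative for equal-length
   sequences costs at least $2(\text{open}+\text{extend}) = 10$ while
   removing $k \le 3$ mismatches recoups at most $2k \le 6$.
3. **Pileup** (`build_pileup()`): per position, `depth_clean` counts reads
   covering the column with neither insertion nor deletion there (the
   exclusion is per column, not per read); insertions anchor to the column
   left of the inserted bases; N columns are excluded from numerator and
   denominator alike.
4. **Profile** (`mutation_profile()`): substitution rate = mismatching reads
   / clean depth; indel rate = indel reads / (clean + indel). Zero-coverage
   positions carry rate 0 plus an explicit `covered = FALSE` flag and are
   excluded from window means — silently averaging zeros would bias low.
5. **Background subtraction** (`subtract_background()`): per-position
   $\max(0, \text{sample} - \text{background})$ on *rates* (depths may
   differ between runs), for substitution and indel rates alike.
6. **Window statistics** (`window_average()`, `per_generation_rate()`,
   `generations_from_passages()`): the window mean divided by the doubling
   count (summed $\log_2$ OD fold changes) gives substitutions per bp per
   generation. The division is linear, matching how such rates are
   conventionally reported; the compounding-correct alternative
   $1-(1-p)^{1/g}$ differs by under 0.2% at these magnitudes.
7. **Combination** (`combine_profiles()`): per-guide profiles re-indexed to
   PAM-relative coordinates — relative 0 is the 3′-most base of the NGG *on
   the protospacer strand*, so template-strand guides are flipped
   (an involution) — and averaged unweighted across guides (a depth-weighted
   option exists but is not the default, since runs are typically sequenced
   to comparable depth and unweighted averaging treats each guide as one
   observation).
8. **Spectrum** (`spectrum()`): per-position ref→alt rates over a window,
   their 4×4 aggregate, and the A/T share of total signal.
9. **Window extent** (`estimate_window_extent()`): the shortest contiguous
   interval of relative coordinates holding ≥ 99% (configurable) of the
   summed mean rate; ties break toward the PAM (smaller |midpoint|), then
   leftmost. On an exactly uniform 100-position profile the minimal
   interval at 99% coverage is 99 positions — equality is accepted within
   $10^{-12}$ to keep the discrete optimum stable under floating-point
   summation.

## Guide bookkeeping and downstream annotation

Guides are named `<distance><L|R>` with a `t` prefix for template-strand
protospacers: the distance from an anchor (we use the first base of the
codon of interest, since an amino-acid "target site" does not pin a single
nucleotide) to the PAM 3′ end, `L`/`R` for left/right along the coding
orientation. The corner case of a PAM 3′ end exactly on the anchor is
reported as `0L` — the convention itself does not define a side there, and
a fixed choice keeps the naming invertible. Only NGG PAMs are scanned
(`find_protospacers()`); N matches any base. `annotate_mutations()` maps
substitutions to codons and amino-acid changes under the standard genetic
code and reports the nearest annotated feature (e.g. a CDR) with a signed
distance, 0 inside.

## Affinity titrations

`fit_saturation()` fits the monovalent single-site isotherm
$\mathrm{signal} = B_\max \, c / (K_d + c)$ by nonlinear least squares with
a deterministic multi-start: $K_d$ begins on a log-spaced grid spanning the
concentration range (12 starts), $B_\max$ at the maximum signal, and the
best converged fit must be at least as good as every grid start. Any
normalization (scaling signals to the fitted $B_\max$) is applied after
fitting — normalizing first would distort the residuals that determine
$K_d$. Fold improvement is the plain $K_d$ ratio. Competitive-staining
corrections and kinetic constants are out of scope.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere in the API and in TSV
  output; SAM I/O is 1-based by definition of the format. BED-like feature
  files are 0-based half-open on disk, as BED is, and converted on read.
* No base-quality filter is applied by default (the merge step already
  arbitrates by quality); pileup construction is count-based.
* The window-extent tie-break and the ±$10^{-12}$ coverage tolerance are
  the only places where floating-point behaviour could move a discrete
  answer; both are pinned by tests against an exhaustive-search oracle.
* `fit_saturation()` refuses fits worse than a grid start rather than
  returning them, so a reported $K_d$ is always a verified optimum over the
  start family.

## What the test and acceptance runs compute

The test suite validates every stage against independent oracles:
a brute-force affine DP for alignment scores, per-read loop recounts for
pileups, exhaustive interval search for the window extent, an independent
codon table for translation, and closed-form binomial/Poisson expectations
for the simulator. End-to-end, simulating at
$r = 2.13\times10^{-4}$, $g = 20.5$ with a uniform ±50 bp window and
recovering the window mean through merge → align → pileup → profile
reproduces the closed form $1-(1-r)^g \approx 4.4\times10^{-3}$
substitutions/bp within Monte-Carlo error, the 100 bp window extent within
discretization, and — with the A:T background multiplier calibrated by
`calibrate_at_multiplier()` so that the expected A/T share of
substitutions is 1.3% given the reference's base composition — an observed
A/T spectrum share statistically consistent with 1.3%.

Problem sizes: the in-suite checks use 10,000–20,000 genomes at 50×–4,000
merged reads; `scripts/acceptance.R` uses 20,000 genomes / 20,000 merged
pairs for the window-mean and extent targets and 400,000 genomes / 200,000
pairs for the A/T share, whose rare-event counting needs the larger sample
for a stable percentage. These are scaled-down analogues of a real
amplicon run (100,000+ reads); all estimators involved are unbiased in
read depth, so depth choices trade Monte-Carlo noise only.

## A worked example

```{r example, eval = FALSE}
set.seed(42)
ref <- random_amplicon(450, gc = 0.45, pam3_pos = 226)
guide <- find_protospacers(ref) |>
  dplyr::filter(strand == "coding", pam3_pos == 226) |>
  name_guide(anchor = 200)

cfg <- simulation_config(ref, guide, base_rate = 2.13e-4, generations = 20.5,
                         n_genomes = 10000, seed = 1)
pool <- simulate_mutagenesis(cfg)
reads <- sample_reads(pool, 5000, seed = 2)

prof <- reads |>
  merge_read_pairs() |>
  align_reads(ref) |>
  build_pileup(ref) |>
  mutation_profile()

window_average(prof, 226, 50) |> per_generation_rate(20.5)
combine_profiles(list(prof), guide) |> estimate_window_extent()
spectrum(prof, 226, 50)
```

## Known limitations

Single-amplicon references only; merged-read analysis only (unmerged pairs
are dropped, not rescued single-ended); no statistical testing between
conditions and no cross-run normalization; the outcome spectrum defaults
are placeholders to be overridden when a measured spectrum is available;
the simulator's independence assumptions (sites, genomes, reads) understate
the correlation structure of real libraries.
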