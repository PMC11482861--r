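---
title: "Rescuing deaminated seeds with a purine/pyrimidine index"
author: "ryseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rescuing deaminated seeds with a purine/pyrimidine index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ancient DNA arrives as short fragments (typically 30-120 bp) carrying a
characteristic chemical scar: hydrolytic deamination converts cytosine to
uracil, read by the sequencer as thymine. In double-stranded library
preparations this appears as C>T substitutions concentrated at the 5' end
of each fragment and, through base complementarity, G>A substitutions at
the 3' end; single-stranded preparations show C>T at both ends. Seed-and-
extend aligners require an exact seed match before extension can begin,
and a single deaminated base inside every candidate seed of a short read
is enough to lose the whole alignment. Because aDNA samples are
low-coverage to begin with, and because it is precisely the damaged
(i.e., demonstrably ancient) fragments that are lost, this failure mode
both discards data and biases downstream damage-rate estimates toward
undamaged molecules (survivor bias).

## The method

Deamination only ever produces transitions: substitutions within the
purine class \{A, G\} or within the pyrimidine class \{C, T\}. Re-encoding
a kmer over the two-letter alphabet \{R, Y\} (purine/pyrimidine) therefore
yields a representation that is *invariant* under any amount of
deamination. `ryseed` exploits this with a pair of indexes:

* a standard **minimizer index**: for every window of `w` consecutive kmer
  start positions on each strand, the canonical kmer (the orientation with
  the smaller Wang 64-bit hash; ties to forward) attaining the window's
  minimum hash is stored with its occurrences. Keys are 2-bit-per-base
  packed integers, so a 62-bit key holds up to 31 bases.
* an **RY rescue index**: the RY projection (1 bit per base, so up to 62
  bases in the same key width) of every minimizer key, mapping back to the
  minimizer keys that produced it. The rescue index is deliberately *not*
  built by re-running minimizer selection in RY space — that would select
  a different kmer set — but by projecting the minimizer set, which
  guarantees every indexed minimizer is reachable through RY space. Its
  payload is a back-pointer only; positions always come from a second
  constant-time lookup in the minimizer index.

At query time a read is windowed exactly as the reference was. Exact
kmer-space hits seed as usual. Additionally, each selected read kmer's RY
projection is looked up in the rescue index (in both orientations — see
*Numerical choices*), producing candidate minimizers that match the read
kmer in RY space but not necessarily in nucleotide space. Since the two
kmers share an RY projection, every mismatch between them is a transition.

### The Bayesian filter

A mismatched candidate has two possible explanations: the locus is right
and the mismatches are deamination (event $M$), or the RY agreement is a
coincidence ($\neg M$). With $m$ mismatches in a seed of length $k$:

* **Spurious model.** Mismatches of a spurious RY match are taken to fall
  uniformly, giving a binomial likelihood
  $P(r \mid \neg M) = \binom{k}{m} p^m (1-p)^{k-m}$ with a power-law
  per-base mismatch rate $p = a k^{b}$, $a = 1.0014$, $b = -0.6628$
  (constants adopted as given from bacterial-read calibration). For
  $k \ge 22$ the empirical mismatch proportion tapers off and the model is
  replaced by a flat $0.01$ regardless of $m$. With these constants $p$
  would exceed 1 at $k = 1$; it is clamped into $[0,1]$ (only $k=1$ is
  affected).
* **Deamination model.** Independent per-base factors over the seed: a
  read-T over reference-C contributes $\delta_{CT}$ at its distance from
  the read's 5' end, a read-A over reference-G contributes $\delta_{GA}$
  at its 3' distance, a matching base over reference C or G contributes
  $1-\delta$ at its position, any other base contributes 1, and any
  mismatch inconsistent with deamination (including the reverse
  transitions T>C and A>G) forces the likelihood to 0. The product runs
  over the seed's $k$ bases — the only sequence compared before extension
  — not the full read.
* **Posterior.** $P(M \mid r) = \dfrac{P(r|M)\,V}{P(r|M)\,V +
  P(r|\neg M)(1-V)}$ with user prior $V$ (default 0.5). A candidate is
  rescued when the posterior reaches the threshold $j$ (default 0.5,
  inclusive). $0/0$ is defined as 0. Exact candidates ($m = 0$) always
  pass; candidates duplicating an exact seed are dropped.

Rescued minimizers join the exact seed set and everything downstream —
diagonal clustering, extension, scoring — is unchanged and operates in
ordinary nucleotide space, so a falsely rescued seed still has to survive
extension, which it rarely does.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 29 bases | minimizer length; larger = more specific, less sensitive |
| `w` | 11 | kmer starts per window per strand; larger = sparser index |
| `a`, `b` | 1.0014, -0.6628 | spurious power-law constants (calibration, not refit here) |
| cutoff / plateau | 22 / 0.01 | flat spurious likelihood for long seeds |
| `V` (`priorV`) | 0.5 | prior on the deamination explanation |
| `j` (`thresholdJ`) | 0.5 | posterior rescue threshold; `j = 1` reproduces the no-rescue baseline |
| `maxHits` | 512 | per-key hit cap at index build (bounds repeat blowup) |
| match/mismatch | +1 / -4 | extension scoring |
| gap open/extend | 6 / 1 | penalties of the banded gapped fallback |
| X-drop | 20 | gapless extension abandon threshold |
| band | 16 bases | cluster diagonal half-width and gapped-fallback window pad |
| score floor | 0.5 x read length | alignments scoring below this fail |
| profile depth | 5 positions/end | damage matrix rows |

The extension defaults were chosen so that a single transition mismatch in
a short read passes the floor comfortably while random 30-mers essentially
never do; they are all exposed as arguments.

## Damage profiles

A `DamageProfile` holds two matrices of per-position substitution rates,
one indexed from each fragment end, with all 12 off-diagonal substitution
columns (`"A>C"` ... `"T>G"`); files are plain TSV with those column
headers. Queries beyond the last profiled row clamp to the last row by
default (`beyondDepth = "zero"` is available), reflecting residual
interior deamination. Double-stranded geometry reads C>T from the 5'
matrix and G>A from the 3' matrix; single-stranded libraries read C>T
from both ends' matrices, combined as $1-(1-r_5)(1-r_3)$ — the two ends
are treated as independent deamination opportunities, a choice made once
here because the geometry alone does not dictate a combination rule.
Non-deamination substitutions are read from the 5' matrix at the
5'-distance; the shipped fixtures are zero there.

Four fixtures ship with the package (`damageFixture()`): `zero`, `ds-mid`
(C>T/G>A decaying 0.25 ... 0.02 over five terminal positions), `ds-high`
(0.45 ... 0.06), and `ss-low` (single-stranded C>T 0.08 ... 0.01 at both
ends). These are package-defined strata with the monotone terminal decay
shape typical of published misincorporation profiles; they are synthetic,
not transcriptions of any measured sample.

## The simulator

`simulateReads()` draws fragments uniformly over a panel (uniform start,
uniformly chosen sequence, Bernoulli(0.5) strand; circular sequences may
wrap the origin), with lengths from an empirical table or a truncated
discretised lognormal. The default lognormal (median 55 bp on [30, 120])
reproduces the short-fragment shape of ancient mitochondrial libraries.
Damage is applied per base in sequenced-read orientation with the
profile's rates and the geometry above. Contaminants (a configurable
fraction) are drawn identically from a user panel or, by default, as
i.i.d. uniform random sequences. Sequencing error is off by default —
matching the filter model, which deliberately does not model it — and
available as a uniform per-base rate for robustness experiments.

What the generator does *not* emulate: NuMT-like homologous contaminants
(its random contaminants are much easier to reject than near-copies of
the target), indels, PCR duplicates, adapters, quality-score structure,
and fragment-end base composition biases. Passing benchmarks here
therefore demonstrate the rescue mechanism's behaviour under clean
deamination, not field performance on real libraries.

A default 16,569 bp circular test reference is generated pseudorandomly at
~44% GC (`syntheticMitogenome()`); it is labelled synthetic and any real
FASTA drops in unchanged.

## Numerical choices

* **Bit order.** First base in the most significant position in both
  encodings, so lexicographic order equals integer order and the RY
  projection is a per-base low-bit extraction (purines are exactly the
  even codes).
* **Hash.** Thomas Wang's 64-bit mix (the `~key + (key << 21)` ladder),
  pinned and versioned as part of the index format.
* **Canonicalisation.** Smaller hash of forward vs reverse-complement
  encoding wins; ties to forward. All kmers tying a window minimum are
  indexed (never loses a seed).
* **Truncated windows.** A sequence (in practice: a read) with at least
  one but fewer than `w` kmer positions is treated as a single window.
  Without this rule, reads shorter than `k+w-1` — common at `k = 29` with
  30-120 bp fragments — could never seed at all.
* **Dual-orientation RY lookup.** Canonical orientation is decided by the
  nucleotide hash, which damage changes; the damaged read kmer can
  canonicalise opposite to its undamaged form. Each selected read kmer
  therefore queries both its RY projection and that projection's RY
  reverse complement (reverse the bits, flip them). This is what makes
  rescue complete: every transitions-only neighbour of every indexed
  minimizer is reachable.
* **Per-pair filtering.** When one RY key backs several minimizers, each
  (read kmer, candidate) pair is filtered independently on its own
  mismatch pattern.
* **Reverse-orientation geometry.** Comparisons are evaluated in read
  (sequenced-strand) orientation — the frame in which deamination
  geometry is defined — by reverse-complementing both kmers first when
  the window matched in reverse canonical orientation.
* **Log space.** Likelihood products are accumulated in logs with
  underflow clamped at 1e-300; structural zeros stay exactly zero.
* **Clustering and extension.** Seeds group by (sequence, strand) and
  chain along the alignment diagonal with single-linkage at +/-16;
  clusters rank by distinct read offsets and the strongest 16 per read are
  extended. Extension is gapless bidirectional X-drop from the cluster
  anchor; only if the read is not fully covered does a banded gapped
  fitting alignment (affine gaps, free reference end gaps) run. Since
  the simulator generates no indels, the gapped path is exercised mainly
  by spurious clusters, which the score floor then removes.
* **MAPQ.** `min(60, round(40 * (1 - s2/s1)))` from the best and
  second-best scores (0 if none) — a package-defined, monotone rule, not a
  probabilistic model. Equal-scoring alignments tie-break to the lowest
  (sequence, position, orientation) for determinism.
* **Circularity.** Indexing extends circular sequences by their first
  k-1 bases; alignment works on the doubled sequence and reports start
  modulo length with a `ZC:i:1` tag when the alignment crosses the origin.
* **Serialization.** Little-endian, magic `RYSEED1`, versioned, keys
  sorted — so index files are byte-deterministic functions of their
  inputs.

## Evaluation conventions

Simulation truth marks endogenous reads as positives. A mapped endogenous
read within 50 bp (inclusive, circular distance where applicable, leftmost
coordinate vs fragment start) of its true location is a TP; mapped
elsewhere, an FP; unmapped, an FN. Contaminants are TN when unmapped and
are counted as FN when mapped — a nonstandard labeling kept verbatim so
the benchmark's printed formulas reproduce; `conventionalLabels = TRUE`
relabels mapped contaminants as FP. Metrics with empty denominators report
`NA`, never 0. Only primary alignments are classified.

## Problem sizes

The shipped test suite exercises the full pipeline at the sizes it was
designed around: a 16,569 bp circular synthetic reference at `k = 29,
w = 11`; 10,000-read simulations for the baseline-equivalence checks
(zero damage, and posterior threshold 1.0, must both be byte-identical to
a no-rescue run); 20,000 endogenous + 5,000 contaminant heavily damaged
reads for the rescue-direction comparison; and 50,000 fragments per
damage stratum for profile-recovery checks. Exhaustive oracles (all
transition neighbours of all indexed minimizers; brute-force window
scans) run on panels of up to a few hundred bases.

## Known limitations

* The reference model is a panel of linear/circular haplotype sequences,
  not a genome graph; there are no graph coordinates and no surjection.
* The spurious-match constants are a fixed calibration; contaminant
  mixtures very unlike that calibration shift the filter's operating
  point (the threshold `j` is the practical control).
* Rescued positions are re-scored as ordinary mismatches during
  extension; a damage-aware extension score would be a natural extension.
* Rescue can only recover a seed whose *selected window kmer* is a
  transitions-only neighbour of an indexed minimizer; damage that changes
  which position wins minimizer selection within a window is out of
  reach, as is any seed containing a true transversion.
* Paired-end data, secondaries beyond the primary record, and
  multi-threading are out of scope.
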