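# ryseed

Damage-aware seed-and-extend alignment of ancient DNA against small
reference panels, with a purine/pyrimidine (RY) rescue index.

## The problem

Ancient DNA comes as short fragments (30–120 bp) scarred by cytosine
deamination: C→T substitutions concentrated at the 5′ end of each
fragment and, in double-stranded libraries, G→A at the 3′ end.
Seed-and-extend aligners demand an exact seed match before extension, so
a single deaminated base inside every candidate seed loses the whole
read. The loss is worst exactly for the most damaged — most
authentically ancient — molecules, which also biases damage-rate
estimates (survivor bias). `ryseed` is for people aligning aDNA reads to
mitogenomes or small haplotype panels who want those reads back, plus the
simulation and benchmarking machinery to quantify the effect.

## The method

Deamination only produces transitions, i.e. substitutions inside the
purine class {A,G} or the pyrimidine class {C,T}. Re-encoding kmers over
the alphabet {R,Y} (one bit per base) is therefore invariant under
damage. Next to a standard (w,k)-minimizer index (2-bit-packed canonical
kmers under Wang's 64-bit hash), `ryseed` keeps a rescue index mapping
each minimizer key's RY projection back to its minimizer keys. A read
kmer that mismatches in nucleotide space but matches in RY space is
admitted through a Bayesian filter comparing, for a seed of length *k*
with *m* transition mismatches:

- spurious-coincidence likelihood
  P(r|¬M) = C(k,m) pᵐ (1−p)^(k−m), p = a·k^b (a = 1.0014, b = −0.6628),
  flat 0.01 for k ≥ 22;
- deamination likelihood P(r|M) = ∏ per-base factors: δ_CT at the base's
  5′ distance for read-T/ref-C, δ_GA at its 3′ distance for
  read-A/ref-G, 1−δ for matching C/G, 0 for anything else, with δ taken
  from user-supplied position-dependent damage matrices;
- posterior P(M|r) = P(r|M)·V / (P(r|M)·V + P(r|¬M)·(1−V)), rescued when
  ≥ j (defaults V = j = 0.5).

Rescued seeds rejoin the normal cluster-and-extend pipeline in
nucleotide space; at j = 1, or with a zero damage profile, output is
byte-identical to a run without the rescue index. The package also
provides a reproducible aDNA read simulator with ground truth, a
damage-profile estimator with RMSE comparison, and
sensitivity/specificity/F1 benchmarking against simulation truth.

## Worked example

```r
library(ryseed)

panel <- syntheticMitogenome(seed = 42)   # 16,569 bp circular test reference
midx  <- buildMinimizerIndex(panel, k = 29, w = 11)
ridx  <- buildRymerIndex(midx)
prof  <- damageFixture("ds-high")         # heavy double-stranded damage

sim  <- simulateReads(panel, n = 2000, profile = prof,
                      contaminantFraction = 0.2, seed = 7)
aln  <- mapReads(sim$reads, panel, midx, ridx, prof)
base <- mapReads(sim$reads, panel, midx, ridx, prof,
                 config = FilterConfig(thresholdJ = 1))  # rescue off
compareRuns(aln, base, sim$truth, panel, labels = c("rescue", "baseline"))
```

```
rescue: TP 1116 FP 0 TN 400 FN 484 | sens 0.6975 spec 1.0000 f1 0.8218
  mapped endogenous 1116/1600, contaminant 0/400
baseline: TP 966 FP 0 TN 400 FN 634 | sens 0.6038 spec 1.0000 f1 0.7529
  mapped endogenous 966/1600, contaminant 0/400
delta (rescue - baseline): TP +150 FP +0 TN +0 FN -150
```

Of 1,600 heavily damaged endogenous reads, the threshold-1 baseline
places 966 within 50 bp of their true locus; enabling rescue recovers 150
more, at zero cost in spurious placements of the 400 contaminant reads
(none map in either run — spurious RY matches fail the posterior filter
or die during extension). Rescued alignments carry provenance tags:

```r
head(subset(aln, !is.na(zr)), 3)[, c("qname", "pos", "cigar", "zr", "zp")]
```

```
         qname  pos cigar zr        zp
9  endo_000009 8720  118M  1 0.7161622
12 endo_000012 9319  107M  1 0.7852886
20 endo_000020 5178   87M  2 0.7007357
```

`zr` counts rescued seeds in the winning cluster and `zp` is their
minimum posterior; `writeSam()` emits these as `ZR`/`ZP` optional tags.

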