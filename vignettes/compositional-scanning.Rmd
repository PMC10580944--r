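---
title: "Compositional scanning of phage genomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional scanning of phage genomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagesig)
```

## The problem

Temperate phages frequently carry modules acquired horizontally from their
hosts. Such modules betray themselves compositionally: every genome has a
characteristic oligonucleotide usage (a "genomic signature"), and a region
recently imported from another replicon tends to deviate from it.
`phagesig` localizes these regions in small (phage-sized) genomes by
sliding-window tetranucleotide analysis, and predicts the replication
origin and terminus from the cumulative GC skew. A seeded Markov-chain
simulator generates chimeric genomes with known foreign inserts so that
every stage of the pipeline can be validated against ground truth without
any external data.

## Tetranucleotide signatures

For a sequence $S$, we first form the reverse-complement extension
$S\,\mathrm{N}\,\overline{S}$ — the sequence concatenated with its reverse
complement, separated by a single N so no counted word spans the junction.
Counting on the extension makes every downstream quantity strand-independent
by construction: a window and its reverse complement give identical counts,
hence identical signatures (tested exactly, not approximately).

Let $N(w)$ denote the count of word $w$ on the extended sequence (words
containing N are skipped and tallied separately). The expected count of a
tetranucleotide $w = n_1 n_2 n_3 n_4$ under the maximal-order Markov model —
the order-2 model that conditions each base on its two predecessors, the
most conservative null consistent with the observed trinucleotide
composition — is

$$E(w) \;=\; \frac{N(n_1 n_2 n_3)\, N(n_2 n_3 n_4)}{N(n_2 n_3)},$$

with the variance approximation

$$\mathrm{Var}(w) \;=\; E(w)\,
  \frac{\bigl(N(n_2 n_3) - N(n_1 n_2 n_3)\bigr)
        \bigl(N(n_2 n_3) - N(n_2 n_3 n_4)\bigr)}{N(n_2 n_3)^2},$$

and the standardized deviation $Z(w) = (N(w) - E(w)) / \sqrt{\mathrm{Var}(w)}$.

Two total conventions remove every reachable division by zero: when
$N(n_2 n_3) = 0$ we set $E = \mathrm{Var} = 0$, and whenever
$\mathrm{Var}(w) = 0$ we set $Z(w) = 0$ ("no deviation measurable"). This
keeps signatures defined on homopolymeric or very short windows. Counts,
not frequencies, feed $E$ and $\mathrm{Var}$; $Z$ is scale-free up to the
variance approximation. All 256-vectors are indexed in lexicographic
A<C<G<T order so signatures are comparable across runs.

On sequences actually generated by an order-2 Markov chain the Z-scores
are close to standard normal; the test suite verifies mean, spread and
tail mass on 100 kb simulations across 20 seeds. This calibration is also
the key to a design decision discussed below.

## The sliding-window correlation profile

The genome is divided into overlapping windows (default 10 kb window, 1 kb
step, truncated terminal windows included — the only reading under which a
40,452 bp genome yields 41 fragments; full-window-only would give 31). For
each window we compute a 256-long tetranucleotide composition vector on
the window's own rc-extension and correlate it (Pearson) against the
whole-genome vector. A window compositionally typical of the genome scores
near 1; a foreign module depresses r.

### Which vectors to correlate

Two variants are implemented, and the choice matters more than it looks:

* **`method = "frequency"` (default)** correlates the raw tetranucleotide
  frequency vectors. Differences at *any* compositional order — GC
  content, dinucleotide bias, genuine tetramer preferences — depress r.
* **`method = "zscore"`** correlates the maximal-order Markov Z-score
  vectors, the classical signature-comparison statistic.

The Z-score variant standardizes each window against that window's *own*
di-/trinucleotide composition. This is exactly what makes it attractive as
a signature of higher-order structure — and exactly what makes it blind to
low-order divergence: a foreign region whose difference is carried by GC
content and short-word usage (the typical situation for a horizontal
transfer between hosts of different GC) produces window Z-scores that are
again unit-normal noise, indistinguishable from the backbone. On synthetic
chimeras built from order-2 Markov models this is provable: the null
calibration above *guarantees* that window Z-vectors carry no signal, the
window-vs-genome Z correlation collapses to the count-sharing level
$\approx\sqrt{L_\text{win}/L}$ for every window, and the scan has no power
at all. The frequency correlation retains low-order information, scores
the backbone near 0.9 and drops sharply inside inserts, and its magnitudes
match what is reported for real phage genomes scanned this way (backbone
0.9+, anomalous modules around 0.8). It is therefore the default; the
Z-score variant remains one flag away for genomes whose foreign content
differs only beyond order 2.

### Calling anomalies

Windows with $r$ below a threshold are flagged and merged into maximal
regions (merged when overlapping or separated by at most one step). The
default threshold is robust: $\mathrm{median}(r) - 3 \cdot \mathrm{MAD}(r)$
(MAD with the usual 1.4826 consistency constant), so a constant profile
flags nothing and no fixed cutoff needs to be guessed; a fixed value can
be supplied for replication attempts.

Correlation is not comparable across window lengths — a truncated 452 bp
terminal window attenuates to $r \approx 0.6$ on a perfectly typical
backbone purely through counting noise. Flagging therefore considers only
windows of at least `min_len` (default: the full window size, capped at
the genome length so that a genome shorter than one window remains
analysable). Truncated windows stay in the profile; they are simply not
eligible as anomalies, nor do they enter the threshold estimate.

Features (ORFs) are scored by the *minimum* r over the windows overlapping
them — a feature is as anomalous as its worst window — and flagged below
the threshold. Because windows are an order of magnitude wider than
typical phage ORFs, a flagged 10 kb window necessarily implicates ORFs up
to one window length away from the true foreign segment; window-level
resolution, not ORF-level resolution, is what this method provides.

## Cumulative GC skew

Leading and lagging replication strands accumulate complementary G/C
biases, so the running sum of $G - C$ along the genome tends to attain its
minimum at the replication origin and its maximum at the terminus. The
normalized per-window skew $(G-C)/(G+C)$ is reported for display (default
500 bp windows, 100 bp step); the cumulative track accumulates raw $G - C$
counts over disjoint step-sized chunks. Accumulating the overlapping
windows themselves would count interior bases `window/step` times and
break the conservation identity (final cumulative value = total
$\#G - \#C$), which holds here for every window/step combination and is
tested. Extreme positions are reported as the 1-based chunk center rounded
half-up to the step grid — hence calls on a round 100 nt lattice — with
ties resolved to the smallest position.

## The synthetic chimera generator

`make_chimera()` emulates the study conditions the analyses target: a
40,452 bp backbone simulated from an order-2 Markov model at GC 57.64%
(the composition of the real temperate *Halomonas* phage assembly this
package was built around), carrying one 6 kb insert simulated at GC 35%
(starting at position 28,000). The ~22-point GC separation produces an
anomaly comparable in magnitude to what is observed for host-derived
modules in real temperate phages; it is an *emulation* of that situation,
not a reproduction of any particular genome. A toy annotation of
consecutive 600 bp ORF tiles (a typical phage gene length) accompanies
each genome so that window-to-feature mapping can be checked against the
known insert interval. One seed drives one RNG stream for backbone and
inserts; identical seeds give identical genomes, and all truth metadata
(insert intervals, model GCs, seed) travel with the output.

What the generator deliberately does **not** emulate: real gene structure,
codon bias, beyond-order-2 tetranucleotide preferences of real genomes,
repeats, or assembly artefacts. Consequently a passing recovery test shows
that the scan finds low-order compositional anomalies of realistic size
and contrast under ideal noise assumptions — it does not show that every
real horizontally transferred module (some of which match their new host's
GC) would be found, nor that flagged regions are really of foreign origin.

## Numerical choices

* Internal coordinates are 0-based half-open everywhere; every
  human-facing table is 1-based inclusive. BED output is 0-based, TSV
  output 1-based, and the two round-trip losslessly.
* Human-facing percentages and correlations are rounded half-up to 2
  decimals (matching the precision such values are conventionally printed
  at); full precision is kept internally.
* A window whose composition vector is identical to the genome's returns
  r = 1.0 exactly (floating-point `cor(x, x)` can miss 1 by one ulp); a
  zero-variance vector yields a missing r, which is excluded from
  thresholds and never flagged. An all-missing profile is an error.
* IUPAC ambiguity codes degrade to N (with a warning count) rather than
  erroring; k-mer windows containing N are skipped and tallied. Multi-record
  FASTA input takes the first record, loudly — phage assemblies are
  expected to be single-contig.
* Sizes used by the validation suite: 100-seed recovery runs on full
  40,452 bp chimeras, 20-seed null calibration on 100 kb simulations,
  property checks on 2–50 bp strings against brute-force enumeration.

## Limitations

* Window-level (10 kb) resolution; insert boundaries and per-ORF calls
  inherit it.
* The frequency-correlation default trades specificity for power on
  low-order divergence; regions unusual only in their beyond-order-2
  structure need `method = "zscore"`.
* Origin/terminus calls assume a replichore-structured skew; genomes
  replicating by mechanisms without strand bias (or packaged linearly
  without a fixed origin) yield extrema without biological meaning.
* Single-contig, linear analysis only; no attribution of anomalous
  regions to donor taxa.
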