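---
title: "Methods: LSH-based read classification and profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LSH-based read classification and profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lshtax)
```

## The model

`lshtax` classifies short reads against a reference library by finding,
for each 32-mer of the read, an approximate nearest reference 32-mer
under Hamming distance, and treating the match distance as evidence
strength. The pipeline has four stages, each with an explicit
mathematical contract.

### Inexact k-mer search

A k-mer (k ≤ 32) is packed 2 bits per base (A=00, C=01, G=10, T=11, base
0 in the low-order bits) and stored canonically (the lexicographic
minimum of the word and its reverse complement), making matching
strand-independent. Bit-sampling LSH extracts, for each of $l$ tables,
the 2-bit symbols at $h$ fixed random positions; each table is a dense
$2^{2h} \times b$ matrix of pointers into the k-mer array $K$. Under the
idealization that sampled positions are independent of mismatch
positions, two k-mers at distance $d$ share at least one table hash with
probability

$$\rho(d) = 1 - \bigl(1 - (1 - d/k)^h\bigr)^l,$$

and a read of length $L$ yields $(L-k+1)\,\rho(d)$ expected matches. At
the production defaults ($k=32, h=15, l=2$) a 150 bp read at 25%
divergence expects 3.2 matches (1.6 with one table); under a "3 expected
matches" usefulness criterion, one table tolerates divergence up to
0.21, three up to 0.27, four up to 0.28 — diminishing returns that
motivate $l = 2$. Lookups compute the true distance of every candidate,
so reported matches are never false; only misses are stochastic.

**Numerical note.** $\rho$ is evaluated at the *continuous* distance
$d_{\text{norm}} \cdot k$. Rounding to an integer distance first would
shift the one-table tolerance figure from 0.21 to 0.20; the continuous
reading reproduces all printed reference values and is the one this
package uses.

**What the recall tests hold fixed.** $\rho(d)$ is an approximation: for
a query at *exactly* distance $d$ and a table sampling $h$ *distinct*
positions, the true collision probability is hypergeometric
($\binom{k-d}{h}/\binom{k}{h}$), measurably below $(1-d/k)^h$ at
mid-range $d$, and overlapping position sets correlate the tables. The
Monte-Carlo acceptance tests therefore construct the setting where the
law is exact — mismatches i.i.d. per site at rate $d/k$ and tables with
disjoint position sets (the `positions` argument of `lsh_index()`) —
and count recall as retrieving the planted neighbor. A hashing or lookup
bug still fails these tests; the approximation error of the formula
itself does not.

### Soft-LCA labels

Storing the full genome set per k-mer is infeasible; storing one hard
LCA collapses to uninformative high ranks whenever a k-mer appears once
in a distant genome. Each stored k-mer instead carries a single 2-byte
taxon ID built probabilistically: while processing genome $g$, a k-mer
occurring in $N_i$ reference genomes updates its label to
$\mathrm{LCA}(\text{label}, \text{species}(g))$ with probability

$$p_u(N_i) = \min\!\left(\frac{w}{\max(N_i + w - s,\, w)} + \frac{1}{s^2},\; 1\right),$$

with defaults $w = 4$, $s = 5$: rare k-mers ($N_i \le s$) are always
labeled, common ones increasingly keep their current label, and the
$1/s^2$ floor leaves every k-mer a nonzero labeling chance. In the
canonical 20-genomes-of-one-genus plus one-outlier scenario
($N_i = 21$, $p_u = 0.24$), the label stays in the genus clade with
probability $(1-p_u)\bigl(1-(1-p_u)^{20}\bigr) \approx 0.757$ — the
Monte-Carlo acceptance test targets exactly this closed form.

Update coins are derived deterministically from (seed, k-mer, genome
id) via a splitmix64 hash, so labels are *exactly* invariant to genome
processing order, a stronger property than the distributional invariance
the scheme needs. Forcing $p_u \equiv 1$ (e.g. $s \to \infty$)
reproduces the hard LCA, which the tests verify against a brute-force
oracle. $N_i$ is precomputed in a separate pass, not a running count.

### Voting

A matched k-mer votes $v(hd) = (1 - hd/k)^k$ for its label — a near
exponential decay; matches beyond $d_{\max} = \mathrm{round}(3p/2) = 5$
(half-up; banker's rounding would give 4) or with an unassigned label
cast nothing. Votes are summed bottom-up over the taxonomy, so
$\bar v(t) = \sum_{x} v_x(t) + \sum_{t' \in C(t)} \bar v(t')$, which
makes $\bar v$ monotone along lineages and conserves mass at the root.
With $\tau = \tfrac12 \max_t \bar v(t)$ (the root total), at most one
taxon per rank can exceed $\tau$; the read is assigned at the lowest
rank whose winner satisfies the *strict* inequality $\bar v > \tau$, so
an exact half-split moves assignment one rank up. Equal-distance label
ties are broken toward the smallest K index (deterministic stand-in for
the "arbitrary" tie-break). Finally, winners with
$\bar v(\hat t) < 0.03$ — less than two distance-4 matches, a regime
dominated by spurious hits — are left unclassified; raising this filter
can only unclassify reads, never reassign them.

### Profiling

Profiles are per rank and independent across ranks. Default mode
normalizes each read's rank-$r$ votes to sum to one before summing over
reads (every read with any votes contributes equally); raw mode sums
$\bar v$ directly and is kept as an option because it estimates evenness
(Shannon's equitability) better even though it is worse on Bray-Curtis.
With the unclassified component (default on), the per-read denominator
is the root total and the residual — votes parked above rank $r$,
evidence for *some* descendant — flows to an artificial unclassified
taxon, so profiles still sum to 1 (asserted to 1e-9). Genome-size
correction divides by the clade-mean reference genome length and
renormalizes; with uniform lengths it is the identity. Unclassified mass
has no genome length, so correction rescales the classified taxa within
their original share and leaves the unclassified share untouched — a
choice the source material leaves open.

Reads the classifier rejects still contribute votes to profiles:
profiling consumes vote tables, not read assignments.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 32 bases | k-mer length; ≤ 32 so one word fits 64 bits |
| `h` | 15 (production), 8–10 in tests | sampled positions per table; table memory is $2^{2h} b l$ 4-byte slots, so desk-scale work uses `suggest_params()` |
| `l` | 2 tables | sensitivity vs memory, linear in memory |
| `b` | 7 slots | bucket width; overflow evicts by per-row reservoir sampling, unbiased in insertion order |
| `p` / `d_max` | 3 / 5 bases | tuned guarantee radius and the voting gate round(3p/2) |
| `w`, `s` | 4, 5 | soft-LCA decay and offset |
| `min_total_vote` | 0.03 | spurious-classification filter |

`suggest_params()` picks the smallest $h \ge 8$ with slot capacity
$2^{2h} b \ge n_{\text{kmers}}\, l$, then lowers $h$ if a memory budget
demands it — a documented simplification of the reference tool's sizing
heuristic, whose full version is out of scope here.

## The synthetic world

`generate_world()` draws a uniform ACGT root genome and evolves one
genome per taxonomy node with i.i.d. substitutions (Jukes–Cantor style:
uniform choice among the three alternatives) at a configured per-level
rate; species leaves become the reference set. Defaults: 1 superkingdom
x 2 phyla x (single class/order) x 2 families x 2 genera x 3 species =
24 genomes of 100 kb, 5% substitutions/site per level — sibling species
then sit at ≈ 9.7% pairwise distance, a realistic within-genus figure —
150 bp reads, 2000 reads per query, 0.5% sequencing error.
`generate_queries()` mutates a donor reference at the requested novelty
rate (the minimum-distance-to-reference axis) and samples error-bearing
reads from both strands.

What the generator deliberately omits: indels (keeping the Hamming-
distance model exact), assembly and chimera artifacts, realistic error
profiles, and log-normal community structure. A green end-to-end test
therefore establishes that the pipeline recovers substitution-diverged
genomes under its own model, not performance on real instruments or real
taxonomies.

## Design choices where the design was open

- **Duplicate detection at insert** uses an exact k-mer→index map rather
  than probing hash rows: after reservoir eviction, row probing would
  re-append k-mers that are still in $K$.
- **Candidate deduplication** across tables happens by K index before
  distance computation, so a k-mer present in both tables is counted
  once.
- **Minimizer mode** (canonical 35-mers reduced to their smallest
  32-mer, consecutive duplicates collapsed) is implemented behind a flag
  and off by default: its tie-break and duplicate policy are not pinned
  down by the source material, and windows over 32 bases cannot use the
  packed codec, so that path canonicalizes on characters.
- **Evaluation of correct-but-less-specific calls**: a read assigned
  above the evaluated rank provides no label there and counts as a miss
  (FN) for represented taxa.
- **Unclassified mass in profile metrics** is treated as a taxon only
  when both compared profiles carry it; otherwise it is dropped and both
  profiles renormalized.
- **Genomes whose species is missing from the taxonomy** are rejected at
  build time with an error naming them.

## Known limitations

- Internal taxon IDs are capped at 65,535 (2-byte labels by design).
- Dense tables make $h > 12$ impractical on desktops; the production
  default $h = 15$ is documented but assumes server memory.
- $\rho(d)$ is an idealization (see above); empirical recall for exact-
  distance neighbors with overlapping tables runs a few percent below it
  at mid-range distances.
- The classifier is single-threaded in R for the vote stage; the C++
  lookup dominates at desk scale regardless.
- Paired-end mates, strain-level deconvolution and Bayesian read
  redistribution are out of scope.
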