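---
title: "Designing precursor-selective 2'-OMe/LNA antisense oligomers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing precursor-selective 2'-OMe/LNA antisense oligomers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seloligo)
```

## The problem

Many miRNA families contain paralogous precursors that release an identical
mature miRNA-5p. Conventional antisense reagents directed at the mature
sequence (or at ~20-25-nt stretches of the precursor) cannot tell such
paralogs apart, because the paralogs typically share near-identical stems
(~90% identity). What does differ is the apical loop: both its length and
its nucleotide composition diverge between paralogs. `seloligo` implements a
design workflow that exploits exactly this divergence: short (default
13-nt) 2'-O-methyl oligomers with three LNA residues, aimed at the region
around the Dicer 5' cleavage bond and the apical loop, where a >= 2-nt
difference between paralogs is available and — at this oligomer length and
chemistry — sufficient for discrimination.

Two candidate geometries are enumerated per precursor
(`enumerate_candidates()`):

* **cleavage_overlap** — every k-mer window that straddles the 5p-arm
  Dicer cleavage bond (with at least `min_side = 2` nt on each side of the
  bond) and overlaps the loop by at least one nucleotide. These oligomers
  both block the scissile bond and reach into the divergent loop.
* **loop_covering** — the single window covering the entire apical loop
  plus `loop_flank = 1` nt on each side. Its length therefore follows the
  loop (an 11-nt loop gives a 13-mer, a 16-nt loop an 18-mer) rather than
  the global `k`.

Only the 5' cleavage bond is targeted by default (`site = "3p"` gives the
symmetric enumeration); arm-selective inhibition of the 5p product was the
design goal the defaults encode.

## Precursor model

A hairpin record carries the RNA sequence, the mature-arm intervals, and an
optional dot-bracket structure. Coordinates are 0-based half-open
internally and 1-based inclusive in every file and report. Two modelling
choices matter:

* **Cleavage bonds come from the arm annotations**, not from the
  structure: the 5p bond is the 3' boundary of the 5p arm, the 3p bond the
  5' boundary of the 3p arm. Annotations are the ground truth a designer
  actually has (miRBase-style coordinates), and this keeps the bonds stable
  under re-folding.
* **The apical loop is the unpaired run enclosed by the innermost base
  pair of the (single) terminal loop.** Bulges and internal loops in the
  stem are *not* part of the apical loop, so "stem" in identity statistics
  means everything outside the apical loop, bulges included. Multibranch
  structures are rejected by name — the model is a hairpin, nothing else.

When no structure is supplied, `nussinov_fold()` provides a fallback: plain
base-pair maximisation over Watson-Crick plus G-U pairs with a minimum
hairpin loop of 3 nt. It is *not* a thermodynamic folder; it exists so that
annotation-only records still yield a loop. Its traceback is deterministic
(pairing of the interval's 3' end preferred, 5'-most partner on ties), and
its pair counts are property-tested against exhaustive enumeration of all
non-crossing pairings up to length 12.

G-U wobble pairs are counted as pairs in *folding* but as mismatches in
*identity and alignment* statistics: folding stability and antisense
complementarity are different questions, and designed oligomers are fully
Watson-Crick by construction.

## Hybridization energetics

Duplex stability is the standard nearest-neighbor sum
$$\Delta G^\circ_{37} = \Delta G^\circ_{init} + \sum_i \Delta G^\circ_{stack}(i)
  + n_{AU\,ends}\cdot\Delta G^\circ_{AU}$$
with the Watson-Crick RNA/RNA parameter set measured in 1 M NaCl at 37 °C,
shipped as a versioned TSV (`nn_rna_1M_NaCl_v1.tsv`) so alternates can be
swapped in. Every entry satisfies
$|\Delta G^\circ_{37} - (\Delta H^\circ - 310.15\,\Delta S^\circ)| \le 0.05$ kcal/mol,
and the loader enforces this. Three deliberate simplifications:

* **Chemical modifications carry no energetic bonus.** 2'-OMe and LNA
  residues are design annotations (`+N` in report strings); the predictive
  model is for the unmodified RNA/RNA duplex, which is also how the
  sequence-only calculators used in this field behave. Predicted energies
  therefore *underestimate* the real affinity of the modified oligomers.
* **No salt correction.** Values are reported at the parameter set's salt
  (`salt_label` is echoed in outputs); assay buffers near 50 mM NaCl will
  show smaller absolute free energies than predicted.
* **Mismatched duplexes are out of scope.** `duplex_energy()` errors on any
  non-WC pair, naming the position. Off-target *energetics* are
  approximated by `cross_hybridization()`, the best perfectly complementary
  ungapped run between two sequences (minimum 4 pairs) — a screening
  quantity, not an internal-loop model.

The melting temperature of a two-state duplex at total strand
concentration $C_T$ is
$T_m = \Delta H^\circ / (\Delta S^\circ + R\ln(C_T/a)) - 273.15$
with $a = 4$ for non-self-complementary and $a = 1$ for self-complementary
duplexes ($R = 1.987\times10^{-3}$ kcal K$^{-1}$ mol$^{-1}$). A
non-negative denominator is reported as "no two-state melting in range"
rather than a number.

`self_structure()` screens each oligomer for competing monomolecular and
bimolecular forms: a hairpin flag (a nested helix of >= 4 pairs in the
maximisation fold) and a homodimer flag (a perfect self-antiparallel
complementary run of >= 5, with the energy of that run). Both thresholds
are exposed; both are screening proxies chosen to be deterministic and
oracle-checkable.

## Off-target search

The search re-implements ungapped, end-to-end, <= v-mismatch alignment
semantics over a k-mer index of the reference transcriptome. The object
aligned is always the oligomer's *reverse complement* (its target site);
user-facing helpers convert internally. Both orientations of the reference
are indexed by default — the conservative screening choice, and what a
general-purpose aligner would do — with `both_orientations = FALSE` for
strand-specific reasoning.

`count_hits()` enumerates the full Hamming neighborhood of the query
($\sum_{i \le v} \binom{k}{i} 3^i$ words — 742 at $k = 13, v = 2$) and sums
posting counts, so counts are exact, not heuristic; a 200-case seeded
property suite checks them against a brute-force all-window scan. Hits
count window occurrences; `per_transcript_hits()` gives the per-transcript
summary. Windows containing ambiguity codes are excluded and counted.

The **selectivity rule**: an oligomer passes when the minimum Hamming
distance between its target site and any window of the sibling precursor
is >= 2 (`selectivity_check()`, threshold configurable). The on/off energy
ratio `dg_on / best cross-hybridization energy against a paralog` is
reported descriptively alongside (values >= 1.5 indicate a comfortable
margin) but is deliberately not a hard filter.

Ranking (`rank_candidates()`) applies hard filters first — selectivity
pass, and no self-structure flags unless `keep_structured` — then sorts by
ascending duplex energy, ascending hits at v = 1, ascending hits at v = 2,
with the sequence itself as a lexicographic final tie-break. The order is
total and contains no randomness, so repeated runs are byte-identical.

## Negative-control design

Control oligomers are not scrambles: they are *transcriptome-null* by
construction. The pipeline enumerates all $4^k$ potential target sites
(2-bit-packed codes; $4^{13} = 67{,}108{,}864$), then iteratively removes
every site that aligns to the reference with at most v mismatches for
v = 0, 1, 2, each round feeding its survivors to the next. The elimination
is performed from the reference side — marking the Hamming ball of every
indexed window in a bitset — which is set-equal to querying each candidate
(Hamming distance is symmetric) but far cheaper whenever the reference is
smaller than the candidate space. At k = 13 the bitset is 8 MB; the in-core
guard allows k <= 16 (0.5 GB). If a round leaves no survivors (as the
v = 2 round does against any reasonably sized reference), the pool falls
back to the survivors of the largest v that kept some — those sites have
no perfect or 1-mismatch target anywhere in the reference.

Survivors then pass three characteristic filters: no mononucleotide run of
three or more; no tandem dinucleotide repeat of three or more units
(`ACACAC`); no homodimer tendency (self-complementary run >= 5, the same
proxy as the design-side screen). "Nucleotide pairs" is read as tandem
dinucleotide repeats — the standard low-complexity reading — and the
homoduplex screen as a run-length rule rather than an energy threshold;
both thresholds are configurable. Finally the surviving sites are
reverse-complemented into control oligomers and `n` of them drawn by
seeded uniform choice, the seed recorded in the output.

One engineering cap: when a survivor set is enormous (small reference,
k = 13), only `max_pool` sequences (default 50,000) are decoded from the
bitset, taken as every *stride*-th survivor in ascending code order so the
sample spans the whole space rather than the poly-A corner. Trace counts
are exact popcounts regardless of the cap, and a warning reports when it
binds.

## Modification pattern

The `"auto"` rule places LNA at 1-based positions $\{2, \lceil L/2\rceil,
L-1\}$ — near both ends and in the middle — with all remaining residues
2'-O-methyl. This is the placement reported to maximise affinity gains for
mixmers of this length; explicit position sets are accepted for patterns
taken from a specific synthesis sheet.

## Synthetic fixtures: what they emulate, what they do not

Because the natural worked-example sequences live in restricted
supplementary material, the package ships two kinds of synthetic inputs,
both clearly labelled synthetic:

* `generate_paralog_hairpins()` / `generate_synthetic_transcriptome()` —
  seeded generators. The paralog generator emulates the geometry that
  makes selective design possible (near-identical stems at a requested
  identity, identical 5p arms, loops divergent in length and composition,
  the second loop A/U-rich); the transcriptome generator plants target
  sites verbatim and decoys at exact Hamming distances, verified post hoc.
  Both are pure functions of their seed.
* `synthetic_premir_pair()` — two *fixed* engineered pairs reproducing,
  through the package's own measurements, the documented statistics of the
  two motivating paralog families: 62/67-nt precursors with 11/16-nt
  loops, 47/51 (92%) stem identity, loop compositions 45.5% G/C and 81%
  A/U, a 2-nt paralog difference at the best cleavage-overlap window,
  morpholino-region identities of 20/25 (80%) and 18/24 (75%), all four canonical oligomer
  targets below -21 kcal/mol, and a self-structured 18-mer loop oligomer;
  plus a 64/65-nt pair with 9/17-nt loops.

Passing tests on these fixtures shows that the *algorithms* implement their
contracts exactly and that the workflow reproduces the worked-example
statistics on inputs engineered to have them. It does not show that the
bundled sequences are the natural precursors (they are not), nor does a
1-Mb uniform-random background reproduce the k-mer spectrum of a real
transcriptome: against ~100 Mb of real mRNA/small-RNA sequence, the v = 0
round removes the large majority of all 13-mers, whereas a 1-Mb uniform
background removes ~3%. The *shape* of the elimination trace (v = 2
leaving nothing, the pool falling back to v = 1 survivors) is reproduced;
the absolute counts are reference-dependent and are documented
expectations, not test assertions.

## Numerical and design choices

* Coordinates: 0-based half-open internally, 1-based inclusive at every
  file boundary (arms TSV, report windows).
* T -> U conversion with a warning; case folded; any other symbol is an
  error at parse time.
* k-mer codes are 2-bit packed, A=0 C=1 G=2 U=3, big-endian, carried as
  doubles at the R boundary (exact up to k = 16) and 64-bit integers in
  C++.
* All randomness flows through explicit integer seeds (`emit_controls()`
  and the fixture generators refuse to run without one); RNG state is
  restored after use, so library calls never perturb a session's stream.
* Degenerate inputs fail loudly: single-base-pair duplexes, empty pools,
  empty post-filter candidate sets (warning plus empty ranking and, in the
  CLI, a non-zero exit), structures that are not single hairpins.
* Problem sizes in the test suite were chosen to keep the full suite
  around a minute while still exercising every exact-equivalence property:
  folding oracles to length 12 (200 cases), hit-count oracles at k <= 10
  (200 cases), elimination oracles at k <= 8, and one full-size k = 13 run
  against a 1-Mb background.

## Known limitations

* Hybridization energies ignore target-site *accessibility* (the
  precursor's own structure competes with the oligomer); an
  accessibility-aware interaction model would re-rank candidates whose
  windows fall in strongly paired stems. The reports log hybridization
  energy only.
* No mismatch, dangling-end or loop thermodynamics: off-target energetics
  use perfect-run screening only, and predicted absolute energies for
  modified oligomers at assay salt are not comparable to measured values
  (both effects are documented above).
* No gapped alignment anywhere: insertions/deletions in an off-target site
  defeat the Hamming model. At 13 nt this is the conventional trade-off.
* Desk-scale references are the tested regime for the k-mer index; a
  whole-genome index would want a disk-backed structure.
* The loop-identity figure between loops of unequal length is not computed:
  there is no alignment-free definition, and gapped alignment is out of
  scope by design.
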