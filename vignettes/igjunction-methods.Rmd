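---
title: "Annotating immunoglobulin V(D)J junctions: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating immunoglobulin V(D)J junctions: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igjunction)
```

## The problem

An expressed immunoglobulin variable region is assembled somatically from
one V, (one D, heavy chain only) and one J germline gene segment. At the
joints, exonucleases trim a few bases off the recombining ends, hairpin
opening adds short palindromic (P) overhangs at *untrimmed* coding ends,
and terminal deoxynucleotidyl transferase inserts non-templated (N) bases.
After rearrangement, activation-induced cytidine deaminase (AID) drives
somatic hypermutation (SHM) across the variable region, preferentially at
WRCY/RGYW hotspot motifs (IUPAC: W = A/T, R = A/G, Y = C/T).

`igjunction` annotates 5'-RACE amplicon reads against a germline set and
decomposes each junction into these parts; it also manages and classifies
germline segments (IMGT-style functionality, RSS scanning, clan
clustering), computes SHM and usage statistics, and ships a seeded
simulator that generates reads with full per-read ground truth so that
every stage can be validated without sequencing data.

## Germline classification

A V gene is **functional** when its FR1-FR3 frame is open, both conserved
cysteines are present, an annotated leader starts with ATG and (when
genomic context is available) a downstream RSS exists; an intact frame
with a conserved-residue or regulatory violation is an **ORF**; a stop or
frameshift makes a **pseudogene**; truncation makes it **incomplete**.
The two cysteines are located positionally: the first-Cys at amino acid
23 from the FR1 start and the second-Cys as the last FR3 codon, or by
projection through a pairwise alignment when a numbering template is
supplied — raw offsets are unreliable once indels accumulate, which is
why the template route exists. J genes are functional iff some frame
carries W-G-X-G (heavy) or F-G-X-G (light) without a preceding stop; the
`TVSS` motif is only an advisory flag because it co-occurs with WGXG
without a defined precedence. D genes are summarized by their open
reading frames.

The RSS scanner uses the consensus heptamer `CACAGTG` and nonamer
`ACAAAAACC` with, by default, at most one heptamer mismatch (the
functionally critical `CAC` held exact), two nonamer mismatches and a
spacer of 12±1 or 23±1 nt. These thresholds are a design choice — the
motif itself is standard immunogenetics consensus — and all of them are
arguments of `find_rss()`. The scanner is checked against a naive
sliding-window Hamming oracle in the test suite.

Clans are single-linkage clusters of V genes at ≥ 0.75 FR1-FR3 nucleotide
identity (the classic V-family convention; configurable). Labels are
assigned in descending clan size with lexicographic tie-breaks, which
makes the labelling invariant to input order.

## Junction decomposition: the attribution convention

Sequence alone cannot always say whether a junction base came from the
germline, from a P overhang or from TdT. The package therefore fixes a
deterministic attribution convention and validates it against an
exhaustive enumeration oracle:

1. **Maximal templated attribution.** The V attribution extends rightward
   from the FR3 alignment end by the longest exact match to the germline V
   3' continuation; the J attribution extends symmetrically leftward.
   Bases claimable by both sides go to V (left precedence).
2. **Trims** are the germline bases beyond the retained ends.
3. **P nucleotides** are recognized only where the adjacent deletion is
   zero, as the longest run (≤ `max_p_len`, default 4) of insert bases
   equal to the reverse complement of the terminal retained bases. The
   cap prevents spurious long palindromes; observed P runs are 0–2 nt.
4. **D** (heavy chains): the longest exact match ≥ `min_d_match`
   (default 5 nt) of any germline D inside the remaining insert, with its
   own trims and P rules. Below the threshold the read simply has no D
   call — with short retained D segments that is a valid outcome, and
   D–D fusion is not modelled.
5. Everything left is **N**. Mismatches never extend templated
   attribution: SHM inside the junction is deliberately counted as N
   rather than guessed back to a germline source.

The concatenation invariant — retained V + P + N (+ P + D + P + N) + P +
retained J reproduces the observed junction byte-exactly — is asserted at
run time on every record. On an exhaustive micro-grid (toy 20-nt V and J,
all trim pairs 0–4, all inserts ≤ 3 nt; 2,125 instances) the decomposition
equals a brute-force oracle that enumerates every consistent split and
applies the same maximal-templated / maximal-P / V-precedence rules. The
instances where the canonical decomposition cannot reproduce the
generating parameters (e.g. an N base that happens to continue the
germline) are intrinsically ambiguous; the tests verify that these are
exactly the oracle's ambiguous set, not decomposition errors.

## CDR3 anchoring

The CDR3 is the segment strictly *between* the conserved second-Cys
(`YYC`) and the J-region Trp/Phe (`WGXG`/`FGXG`) — both anchor codons
exclusive. "Between" is read literally and exported as such; the
convention is fixed and stated rather than inferred, since length
statistics are internally consistent under either reading. Anchors are
placed by projecting the germline anchor codons through the V and J
alignments, so a somatic mutation inside an anchor codon does not move
the interval; a motif scan (one amino-acid mismatch allowed at
non-critical positions, the C and W/F fixed) is the fallback when no
projection exists. Records without locatable anchors are flagged
`cdr3_missing` and excluded from CDR3 statistics, never silently dropped.
CDR3s of ≥ 40 amino acids are flagged `ultralong` (threshold
configurable); no structural modelling of the ultra-long stalk-and-knob
architecture is attempted.

## SHM statistics

SHM frequency is observed mutant bases over aligned (non-gap, non-N)
bases across FR1-FR3, as a percentage, overall and per germline V group.
Reads with tied V calls are excluded by default because their mutation
sets depend on the chosen tie member. Indels inside FR1-FR3 are not
counted as SHM events (substitutions only), and sequencing error is not
separated from SHM — a documented limitation; a separate uniform error
channel exists in the simulator (default 0) for sensitivity checks.
Per-site profiles, the 12-class substitution spectrum and hotspot
analyses all derive from the same per-record mutation sets, and the test
suite asserts their mutual conservation. Both hotspot nomenclatures are
implemented (`WRCY`/`RGYW` classic, `WRCH`/`DGYW` generalized); the
default motif set is `{WRCY, RGYW}`, with the others one argument away,
because the two conventions circulate interchangeably in the field.

## The simulator and what it does (not) emulate

`simulate_repertoire()` draws, per read: segments by configurable weights
(default heavily biased J usage 0.95/0.04/0.01, uniform functional V);
trims from empirical tables — heavy-chain V 3' deletions concentrated at
0/2/3 bp with a maximum of 8, J 5' deletions at 0/3/6 bp with a maximum
of 12, light-chain trims mainly 0–3 bp; P lengths 0–2 at untrimmed ends
only; N lengths short for light chains and longer for heavy chains; SHM
as a per-base Bernoulli over FR1-FR3 (default rate 5%) with a 3× CDR
multiplier and a 5× hotspot multiplier; and a transition-biased
substitution spectrum. The tables are empirical transcriptions of
qualitative repertoire observations (modes and maxima rather than fitted
pmfs) and are all config-overridable. Reads are decorated with the
5'-RACE forward primer, a constant-region stub and the locus-specific
reverse primer, so the QC stage sees realistic amplicons.

Per-position mutation rates are scaled as `rate = shm_rate * 4 *
w_out(base) * multipliers`, where `w_out` is the total outgoing spectrum
weight of the base. Under this scaling the marginal substitution-class
fractions equal the configured spectrum weights and the mean rate equals
`shm_rate` exactly when base composition is uniform; the toy germline
cores are generated with near-uniform composition for this reason. With
a non-uniform real germline the realized spectrum shifts with
composition — a property of any per-base mutation model, stated here so
spectrum recovery checks are run with the toy set.

Ground truth records segment choices, trims, P/N strings, the true CDR3
interval and every SHM event; `replay_truth()` reassembles each read
byte-exactly from its truth row, which the tests assert for every read.

What the simulator does **not** emulate: indels, gene conversion,
class-switch recombination, D–D fusion, PE300 merge artifacts, quality
score structure, or a sequencing-error channel distinct from SHM.
Passing recovery tests on simulated data therefore validates the
annotation logic and its statistics, not robustness to those real-data
phenomena.

## Validation design and problem sizes

The validation suite runs entirely on generated data: the junction
micro-grid (2,125 instances), annotated runs of 2,000 reads for usage and
CDR3 recovery (at 2% SHM, a realistic light-chain-like rate that keeps
the focus on usage rather than mutation load), 2,000-read runs each for
SHM-rate (5%, multipliers off), spectrum (A→G weight 0.30) and hotspot
(5× multiplier) recovery, 4,000 trim draws for pmf reproduction, and 100
seeded sequences for the RSS oracle. Statistical recovery checks use
three-standard-error bands (binomial or multinomial as appropriate);
spectrum recovery uses a two-percentage-point band dominated by the
residual composition imbalance of the toy cores. Trim-pmf reproduction is
checked on the simulator's ground-truth draws: inferring trims back
through the junction necessarily folds in the attribution ambiguity
discussed above, which the oracle-equivalence and reconstruction checks
already cover exactly.

Two further conventions matter for reproducibility: all randomness flows
from a single integer seed per run (the simulator restores the caller's
RNG state afterwards), and pipeline outputs contain no timestamps, so
reruns with identical inputs are bit-identical — asserted by hashing in
the tests.

## Known limitations

* Tie handling reports ambiguity (clan-level calls) rather than
  resolving SHM-heavy reads straddling near-identical germline genes.
* Junction-inferred trim distributions are biased toward smaller trims by
  maximal templated attribution whenever N bases continue a germline end;
  the package reports what is identifiable and flags what is not.
* Functionality classification depends on region annotations (or a
  numbering template); leader splice-site prediction is out of scope
  beyond presence/absence of an annotated leader.
* Usage percentages are reported over assigned reads with unassigned
  counts alongside; no clonotype deduplication is applied by default,
  and repertoire-diversity indices are out of scope.
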