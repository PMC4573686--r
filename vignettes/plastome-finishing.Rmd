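---
title: "Finishing a chloroplast genome from long reads: models and methods"
author: "plastidkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finishing a chloroplast genome from long reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Plant whole-genome long-read datasets contain a sizeable admixture of
chloroplast reads: plastid DNA is present in many copies per cell, so even
a low-coverage nuclear run yields plastome coverage in the hundreds to
thousands. plastidkit assembles the finishing workflow around such reads:
pull the plastid reads out of the pool by homology to a related species'
plastome, resolve the physical structure of the assembled molecule, validate
and repair its element order with long-insert mate pairs, polish it, and
compare it against an existing assembly with read-based arbitration of each
disagreement.

Two properties of the chloroplast genome drive the design. First, it is
circular, so every linear representation is an arbitrary cut: mapping,
coverage and comparison must all be circle-aware. Second, it is
quadripartite — LSC–IRa–SSC–IRb, with the two inverted repeats (IRs) about
25 kb each. The IRs are longer than typical long reads, so read data alone
cannot orient the SSC relative to the LSC; only jumps spanning a whole
repeat (here, ~40 kb fosmid inserts end-sequenced with high accuracy) carry
that information. This is the central limitation the mate-pair module
addresses, and it is why a pathological dataset with no repeat-spanning
pairs yields "insufficient evidence" rather than a decision.

## Mapping model

The internal mapper (`index_reference`, `map_read`) follows the standard
long-read recipe: canonical (strand-least) minimizers with k = 15, w = 10;
matching minimizers grouped by strand and diagonal into chains; the best
chain defines a target window into which the whole read is aligned by
banded dynamic programming. Chain score is anchor count minus a penalty for
diagonal spread, ties broken by leftmost target start. Only the best chain
is extended unless `max_hits` asks for more (used to detect ambiguous
anchors inside the IRs).

Alignment identity is defined as matches / alignment columns, with columns
= matches + mismatches + inserted + deleted bases. This definition is used
everywhere: the mapper's floor (0.60, a pre-filter below which hits are
noise), the extraction threshold (0.80), and repeat verification.

The alignment kernel is an affine-gap (Gotoh) banded dynamic program with
integer costs: match 0, mismatch 4, gap open 3, gap extension 4 (a gap of
length L costs 3 + 4L). Unit-cost (Levenshtein) alignment is unusable here:
with random flanks, a long insertion can be rearranged across chance
matches into many equal-cost fragments, which destroys difference calling.
The affine parameters were chosen so that (i) a contiguous gap is always
cheaper than the same bases scattered over several gaps, (ii) an isolated
single-base indel is cheaper than re-expressing it as a substitution plus
an enlarged neighbouring gap (gap open < mismatch), and (iii) a run of k
substitutions is cheaper than any gap-pair rewriting of it. The band is
widened automatically (doubling) whenever the traceback touches the band
edge, within a memory budget; reads so long that no feasible band fits the
budget are reported unmapped rather than failing the run.

Circularity is deliberately **not** handled inside the mapper. Callers
rotate or wrap-extend the target: read classification wrap-extends the
(circular) reference, mate-pair validation wrap-extends the assembly, and
the coverage module maps against two linearizations (below).

## Simulated data: what it emulates, and what not

`sim_config()` defaults are the study conditions: a 150 kb circular
plastome (83 kb LSC, 25 kb IRs, 17 kb SSC, i.i.d. uniform base
composition), long reads with log-normal lengths matching mean 3213 bp and
N50 4713 bp, 11 % i.i.d. per-base errors split
insertion:deletion:substitution = 5:3:3, fosmid-end pairs with
Normal(40 kb, 3 kb) inserts and 700 bp Sanger-accuracy end reads
(substitution rate 5×10⁻⁴), and a nuclear background carrying plastid
insertions (NUPTs) at 2–10 % divergence. The log-normal parameters have a
closed form: the N50 of a log-normal is the median of its length-biased
version, exp(µ + σ²), while the mean is exp(µ + σ²/2), so σ² =
2·log(N50/mean). Reads shorter than 100 bp are suppressed, mirroring
instrument-side subread filtering. Each generator draws from its own seeded
stream, so requesting more reads never perturbs the simulated mate pairs.

The simulator does **not** model chimeric reads, adapter artifacts,
base-quality structure, GC bias, or context-dependent error hotspots.
Passing tests therefore demonstrate the pipeline's logic — classification
thresholds, circular geometry, orientation diagnosis, consensus voting —
under random-error conditions, not robustness to the systematic artifacts
of any particular instrument.

## Extraction operating point

A subread is plastid-like if any mapping to the heterologous reference
reaches identity ≥ 0.80 (inclusive). Whitelisting happens at the
polymerase-read level: one matching subread recruits all subreads of its
hole. At the simulated conditions (reference 5 % diverged, reads at 11 %
error) plastid reads sit near identity 0.85 with a narrow spread, so the
0.80 threshold passes nearly all of them while random nuclear sequence
stays far below the 0.60 mapper floor; measured recall is ≥ 0.98 with
precision ≥ 0.99. NUPT-derived reads at moderate divergence *do* pass the
filter by construction — they are true homologs — and are left to the
polishing majority vote, where the genuine plastid reads outnumber them.

## Structure: boundaries are defined up to chance continuation

IR detection matches opposite-strand minimizers of the same canonical
k-mer; for a true inverted repeat these pairs share an anti-diagonal
(pos_a + pos_b constant). The dominant cluster is re-phased on its modal
anti-diagonal and extended outward base by base from a central seed pair,
keeping the two copies stepping together; the extension is trimmed back to
the last run of 10 consecutive matching columns. A subtlety worth stating:
on a circle, the "true" repeat boundary is only defined up to chance — with
probability 1/4 per end the flanking bases happen to continue the repeat,
so two rotations of the same molecule can legitimately disagree by a base
or two. Detection is therefore exact on a fixed linearization but
rotation-invariance holds only up to a few base pairs of jitter, and the
tests assert it at that tolerance. Mutation *inside* a repeat copy is
tolerated (substitution-type divergence leaves the anti-diagonal intact);
indel divergence between the copies would truncate the greedy extension and
is out of scope.

The partition labels the larger inter-repeat segment LSC, rotates the
molecule so the LSC starts at position 0, and names IRa the copy following
the LSC. Equal-length segments raise an error asking for explicit labels.
The "established start" is operationalized as a user-supplied anchor
sequence (for example the first 500 bp of a reference) rather than a
hard-coded gene convention; anchors inside an IR map twice and raise an
ambiguity error.

## Mate-pair geometry and the SSC decision rule

Distances are start-to-start on the circle: `(s⁻ − s⁺) mod L` with both
starts leftmost. This convention reproduces printed clone geometries
exactly, including pairs wrapping the origin. A pair is *consistent* when
the strands are opposite and the distance falls in the insert window
(default 25–50 kb around the ~40 kb jumps). Mates inside an IR are flagged
ambiguous — the copies are interchangeable, so such pairs are tallied
separately and excluded from orientation evidence.

`diagnose_ssc_flip` re-evaluates every pair against a *virtually* flipped
molecule: SSC-internal mates get mirrored coordinates and inverted strand,
everything else is untouched, so no re-mapping is needed. A flip is
recommended only if the inconsistent count strictly decreases **and** the
post-flip consistency of SSC-involving pairs reaches the pre-flip
consistency of pairs not touching the SSC. On correct assemblies the first
condition cannot hold, which is what makes the rule specific.

## Coverage and polishing

Circular coverage maps the reads twice — against the assembly as given and
against a half-rotated copy — and splices the first and last `end_window`
(default 7000) positions from the de-rotated second track. Reads spanning
the cut map partially in the first linearization; since their partial hits
only affect the replaced end windows, they are kept.

Polishing is a plain majority pileup: reads are projected onto assembly
columns through their alignments (no realignment), each column emits the
plurality base with ties keeping the assembly base, deletions win when they
are the plurality, and an insertion between columns is emitted when more
than half the reads spanning that junction carry exactly the same inserted
string (ties toward no insertion). Columns under `min_coverage` (default 5)
are left unchanged and flagged. This is a deliberately simple stand-in for
probabilistic consensus models: at 50× and random errors it corrects
essentially all isolated errors (the acceptance test plants 200 point
errors and requires ≥ 99 % corrected), but it inherits the usual weakness
of column-wise voting in long homopolymers under indel-rich errors.

## Assembly comparison

Anchors are k-mers (k = 21) occurring exactly once in *each* assembly;
inside the IRs k-mers occur twice, so no anchors form there and the
enclosing segment is bridged by banded DP — which is safe precisely because
the two copies are near-identical. A longest strictly-increasing chain
(patience LIS) makes the anchor set collinear; anchors are thinned to a
minimum spacing and checked for non-overlap. Between anchors, equal
substrings short-circuit to all-match; everything else goes through the
affine kernel with the band sized from the length imbalance and widened on
demand. The result is a true global alignment whose score and difference
list match full exact DP on diverged random pairs (the test suite checks 50
pairs up to 6 kb at up to 5 % divergence, plus an independent edit-cost
cross-check against `Biostrings::pairwiseAlignment` under the same cost
scheme).

Differences are maximal non-match runs split into typed events
left-to-right; indels are then left-aligned — shifted left through matching
flanks while the shifted allele is unchanged, possibly into adjacency with
the previous event. The left-alignment makes the placement canonical across
equal-score alignment paths, which is what allows difference lists from
different alignment routes to be compared verbatim. Reported positions are
1-based (internal coordinates are 0-based half-open everywhere; conversion
happens only at the report boundary).

Arbitration maps the high-accuracy reads to assembly A as single-end reads,
takes every read spanning a difference with 10 bp of flank on both sides,
projects the read substring over the locus, and compares it *exactly*
against the two local haplotypes; the verdict needs at least 3 informative
reads and a strict majority. Exact comparison is the right tool at Sanger
error rates and is what distinguishes homopolymer-length alleles reliably.

The package ships the published 23-entry difference table between the
long-read sugar beet chloroplast assembly (cp_2320) and the earlier
short-read assembly (`load_difference_table()`), and a reconstruction
experiment (`difference_recovery_experiment()`) that applies those edits to
a seeded random 149,722 bp background and re-calls them. One table row is
ambiguous between a 6 bp and a 1 bp substitution; we adopt 6 bp, the
reading consistent with the published summary counts (14 single-position
differences, 7 of 2–6 bp, two longer). Substituted and inserted alleles are
drawn to differ from the local background within a ±2 bp shift window —
without that constraint the reconstruction would occasionally plant edits
that genuinely admit a cheaper alignment than the intended one, and no
correct aligner could recover the intended list.

## Numerical choices and degenerate inputs

* Alignment costs: match 0, mismatch 4, gap open 3, gap extend 4 (see
  above for the three ordering constraints that fixed them).
* Thresholds: extraction identity 0.80 inclusive; mapper floor 0.60; IR
  search min_len 1000 at min_identity 0.95; circularity max_error 0.05.
* Tie-breaks: chain ties by leftmost target start; consensus ties keep the
  assembly base; insertion-consensus ties emit nothing; traceback prefers
  diagonal, then query-gap, then target-gap.
* Degenerate inputs: `ir_len = 0` plastomes yield no partition and
  downstream structure functions refuse politely; zero reads give zero
  coverage tracks and identity polishing; zero mate pairs give an empty
  report and an "insufficient evidence" flip diagnosis; constant coverage
  makes the coverage–identity correlation degenerate (reported 0 with a
  flag).

## Problem sizes in the test suite

Unit tests run on a proportionally scaled ~15 kb plastome (8.3/2.5/1.7 kb)
so the whole suite stays interactive. The acceptance-level tests use the
full study conditions where the quantity demands it: the difference
reconstruction at 149,722 bp; SSC-flip recovery across 20 replicates of the
150 kb default plastome with 50 fosmid pairs each; extraction at 250
plastid + 150 nuclear reads against the 150 kb reference; polishing of a
30 kb molecule at 50× with 200 planted errors; circular coverage of a
20 kb circle at 50×. These sizes are the package's chosen trade-off between
statistical resolution and an interactive test cycle.

## Known limitations

* The mapper reports one (or `max_hits`) contiguous alignments per read —
  no split/supplementary alignments; reads spanning the linearization cut
  of a *linear* target are penalized rather than split, which is exactly
  the behaviour the dual-linearization coverage exploits.
* IR boundary detection assumes substitution-type divergence between the
  repeat copies.
* Polishing is column-wise majority voting, not a probabilistic consensus;
  quality values are carried through I/O but never used in scoring.
* Difference arbitration compares spanning substrings exactly; reads with
  an error inside the locus window count as ambiguous rather than being
  partially matched.
* The simulator's error model is i.i.d.; none of the acceptance results
  speak to systematic sequencing artifacts.
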