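---
title: "Clone-by-clone assembly at desk scale: models, parameters and design choices"
author: "clonetiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone-by-clone assembly at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetiler)
```

## The problem

High-quality plant reference genomes such as the ZS97 and MH63 *indica* rice
assemblies were built clone by clone: a deep BAC library is fingerprinted into
a physical map, a minimum tiling path (MTP) of clones is picked, MTP clones
are pooled and sequenced with long reads, each pool assembly is resolved back
into individual circular plasmids and identified, and the identified inserts
are stitched into chromosome-scale pseudomolecules, with whole-genome-shotgun
(WGS) contigs bridging the remaining gaps. `clonetiler` re-implements this
entire chain at desk scale and validates it end to end on synthetic genomes
for which the truth is known exactly.

## The simulator and what it emulates

The generator is first-class, tested code. Its defaults are the study
conditions used throughout the test suite and the acceptance script:

* a 2 Mb genome in two 1 Mb chromosomes of i.i.d. uniform DNA, optionally
  with planted dispersed duplications (`repeat_fraction`, default 0);
* a HindIII BAC library at 10x clone coverage with 40 ± 5 kb inserts (a
  ~1/3-scale stand-in for the real ~117–125 kb inserts, chosen so the whole
  pipeline runs in well under five minutes on one CPU); insert endpoints snap
  to the nearest genomic AAGCTT occurrence, emulating a partial digest, and a
  site is planted when none lies within two standard deviations. Chromosome
  ends count as valid fragment boundaries, so coverage reaches the tails;
* a 7.5 kb circular vector with a single HindIII cloning site, emulating
  pAGIBAC1;
* pool "assemblies": per clone, the circular plasmid linearized at a random
  rotation with its first 600 bp duplicated at the 3' end — the signature by
  which a long-read assembler announces a circular molecule — plus 0.05%
  substitution noise. A configurable `fail_rate` yields truncated linear
  fragments (the redo rate of real pools is not published; the knob is free);
* error-free WGS contigs from random genome fragmentation.

The error model is substitutions only (an indel flag exists but defaults to
off): every identity threshold downstream is exercised by substitutions
alone. Real data additionally carry indels, chimeric clones, cloning bias and
uneven pool coverage, none of which are modelled; a green test suite
therefore demonstrates the *logic* of the pipeline, not robustness to every
artifact of real libraries.

## WGP tags and deconvolution

Tags are the 50 bases immediately 3' of each EcoRI site on each strand (the
left flank is reverse-complemented, i.e. read off the minus strand), emitted
only when the flank reaches 50 bp without an intervening MseI site. Under
this convention the tag set of a sequence is strand-invariant, which the
property tests assert. Tags are compared by exact string equality everywhere
(`tagMatchIdentity = 100%` taken literally).

3D pooling observes each tag in the plate, row and column pools of every
well that contains it; a tag is deconvolved to an address only when exactly
one pool of each dimension saw it. This simple rule is exact on
collision-free libraries (each tag in one clone), which is how the operation
is tested. At 10x coverage most tags lie in many overlapping clones and
would be ambiguous under any per-tag rule, so the full pipeline builds clone
tag profiles directly from the simulator's truth tag map — the per-clone
in-silico digestion that aggregate WGP tagging delivers in practice.

## The physical map

Because tags are matched exactly (tolerance 0), the classical Sulston
fingerprint-band probability degenerates to an exact hypergeometric tail:
the score of two clones with profiles of sizes $k_a$, $k_b$ sharing $m$ tags
in a universe of $N$ tags is $P(X \ge m)$, $X \sim \mathrm{Hyp}(N, k_a,
k_b)$. An oracle test checks this against exhaustive enumeration for every
universe up to $N = 12$. The cutoff cascade is the published one: build at
$10^{-15}$, DQ splitting at $10^{-18}/10^{-21}/10^{-24}$ (a split is kept
only if it yields at least two components of at least two clones),
ends-to-ends merging at $10^{-9}$ (three terminal clones per end, best pair
first) and singleton incorporation at $10^{-12}$.

Within-contig ordering was genuinely open (the fingerprint-ordering
internals of FPC are not described at this level). A greedy
"append-best-to-terminus" seriation was implemented first and measurably
scrambled layouts whenever a contig contained duplicate-interval or
contained clones — which endpoint snapping makes common at 10x. The package
therefore orders clones by spectral seriation: the Fiedler vector of the
graph Laplacian of the shared-tag similarity matrix, the standard layout
method for interval graphs, with a lexicographic sign convention for
determinism. Positions remain in tag units (tags placed before a clone that
it does not carry), forced non-decreasing.

MTP selection is greedy farthest-reach over those positions, requiring at
least `min_mtp_shared = 5` shared tags between consecutive picks (echoing
the clone-identification minimum) and strict position progress, so contained
and duplicate clones are never selected. A final sweep-up appends any clone
still carrying tags the path lacks: position ties at layout ends can
otherwise hide real reach, and with the sweep the MTP provably covers every
tag its contig covers. A physical map remains blind *beyond* its terminal
tags; the consequences surface in the tiling stage below.

## Pool post-processing

Circularization detects the longest prefix–suffix self-alignment spanning at
least 500 bp at 95% identity and terminal on both ends. Candidate offsets
come from exact 24-mer seeds sampled near the 5' end and located near the 3'
end; with a substitution-dominated error model the true offset is exact and
the modal vote is the alignment, so identity is computed positionally over
the full span (indel-containing windows would fall back to
`Biostrings::pairwiseAlignment`; quadratic alignment of 40 kb windows is
never attempted). One overlap copy is trimmed and the circle is
canonicalized to its lexicographically minimal rotation, making all
rotations of one plasmid identical by construction.

Vector excision locates the vector body (the vector minus its cloning site)
in the doubled circular sequence on either strand, requires 95% identity
over at least 90% of its length, flags two-copy (chimeric) and vector-free
circles, and returns the insert linearized at the vector junctions with the
junction-adjacent AAGCTT reading forward.

Clone identification matches the insert's own WGP tags exactly against every
profile. A clone qualifies at `minCloneTagNumber = 5` matched tags covering
`tagMatchPercent = 80%` of its profile. Two deliberate refinements of the
printed rule, both forced by observed failures on nested and twin clones:

* among qualifying candidates the *matched count* is maximized rather than
  the percentage — a clone nested inside the insert always matches 100% of
  its own profile and would otherwise beat the true clone whose percentage
  is dented by sequencing errors; the percentage stays as the qualifying
  filter and the tie-break;
* qualifying members of the insert's own sequencing pool outrank
  out-of-pool candidates, and residual exact ties (byte-identical twin
  clones) are broken by pool membership. Out-of-pool assignment still
  happens when no pool member qualifies, which is precisely how re-arraying
  errors and contamination are caught and labelled `non_mtp_clone`.

BES alignment (98% identity over the full read, inner-facing pair — the
orientation requirement is this package's addition, switchable) is used only
when tags are unavailable, as printed.

## Pseudomolecules

Pieces are anchored to a guide reference by exact 31-mer voting on both
strands; the guide determines order and orientation only and contributes no
sequence. Within each physical-map contig the anchor order must agree with
the MTP walk order; a discordant piece is flagged, and re-placed by neighbor
interpolation only when its anchoring was itself ambiguous (multi-mapping) —
an unambiguous anchor is never overridden, because vote evidence is
stronger than an interpolation.

Neighbors merge when a terminal overlap spans at least 1000 bp at 99%
identity (ends within a 25 bp slack; the search window is capped at 200 kb).
Exactly one copy of the overlap is kept: the clean copy when exactly one
contains Ns, otherwise the upstream copy — a deterministic stand-in for the
published "no preference". Merging is a deterministic left-to-right fold;
the interactive curation of the original pipeline is replaced by rules plus
warnings. Open gaps are written as 100 N (AGP gap type `contig`, linkage
`yes`, evidence `map`; the original work states no gap-size convention).

Gap filling admits only WGS contigs that *fully connect* two neighboring
runs — a terminal overlap against both flanks — inserting the contig minus
both overlap copies (BAC copies always retained) and reducing the contig
count by exactly one per filled gap. When the bridge shows the flanks
themselves overlap, the duplicated prefix of the right flank is dropped.
Additionally, pseudomolecule *ends* are extended by contigs overlapping one
end terminally: the physical map cannot see past its terminal tags, so
chromosome heads and tails are otherwise unrecoverable by any coverage. End
extension uses the same span and identity thresholds, single-sided.

## Statistics

`assembly_stats()` reproduces the release-table semantics exactly:
statistics over sequences strictly longer than 500 bp; N50 is the length at
which the descending cumulative sum first reaches half the filtered total
(boundary counts as reached); the companion columns are counts of sequences
at least that long — the published tables head these counts "NG50/NG90",
which the footnotes define as counts, so the package names them
`count_ge_n50`/`count_ge_n90`. Percentages round half away from zero to the
printed precision.

## Worked example

```{r pipeline, eval = FALSE}
res <- run_pipeline(default_config(), seed = 1)
res$metrics[c("circularization_rate_pct", "clone_id_accuracy_pct",
              "identity_pct", "length_err_pct")]
#> $circularization_rate_pct  [1] 100
#> $clone_id_accuracy_pct     [1] 100
#> $identity_pct              [1] 99.9476
#> $length_err_pct            [1] 0
```

At the default scale this runs in well under a minute: 500 clones, ~100 MTP
clones in row pools of 12, every non-truncated unitig circularized, every
circularized unitig assigned to its truth clone, and both chromosomes
reconstructed at > 99.9% identity and exact length.

## Problem sizes used by the tests

The unit tests run the map stages on a 400 kb single-chromosome library
(100 clones) and the full round trip on the default 2 Mb configuration; the
acceptance script runs the same 2 Mb configuration once. These sizes were
chosen as the smallest at which every phenomenon the pipeline must handle
(duplicate and contained clones, map contig breaks, tag-blind ends,
multi-contig chromosomes) actually occurs.

## Known limitations

* No indel error model by default; identity computation is positional at
  seed-voted offsets.
* No chimera, cloning-bias or read-level simulation; consensus accuracy of
  real long-read assemblies is out of scope.
* Spectral seriation orders duplicate-interval clones arbitrarily (their
  order is genuinely undetermined by tags).
* The 3D deconvolution rule is per-tag presence/absence; it does not attempt
  the combinatorial multi-clone deconvolution a production WGP pipeline
  layers on top.
* Real-data magnitudes (hundreds of Gb of reads, physical-map N50s near a
  megabase) are not reproduced at desk scale; the oracle, round-trip and
  threshold-sharpness properties stand in for them.
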