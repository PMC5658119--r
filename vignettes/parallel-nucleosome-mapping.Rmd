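---
title: "Parallel chemical and MNase mapping of positioned nucleosomes"
author: "parnuc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parallel chemical and MNase mapping of positioned nucleosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parnuc)
```

## The measurement this package models

Micrococcal nuclease (MNase) preferentially cuts linker DNA between
nucleosomes, so the stretch *protected* from digestion in chromatin —
relative to a naked-DNA control digest — marks the nucleosomal footprint.
But MNase is sequence-biased (it favors cutting 5′ of A·T base pairs) and
trims fragment ends, so a footprint alone can misplace a nucleosome.
Site-directed chemical cleavage is the complementary readout: with serine
47 of histone H4 mutated to cysteine and conjugated to a copper–
phenanthroline reagent, Fenton chemistry generates hydroxyl radicals that
cut the DNA backbone close to the nucleosome center (the S47C residues
sit near superhelix location ±0.5, flanking the dyad). Running both
digests on the same chromatin and reading them out on gels — indirect
end-labeling for an overview, primer extension for base-pair resolution —
gives each nucleosome two independent coordinates: an MNase-protected
interval (the particle's extent) and a chemical center (its dyad).

`parnuc` implements the analysis layer of this parallel-mapping design:
circular-coordinate arithmetic for minichromosome substrates, gel-lane
densitometry calibration, strand-resolved cleavage pileups, nucleosome
inference, and seeded simulators that generate every input with known
ground truth. The canonical substrate is the 1,453-bp circular TRP1ARS1
minichromosome (`trp1ars1_fixture()`), colinear with coordinates
461,740–463,192 of *S. cerevisiae* chromosome IV, with seven positioned
nucleosomes and two nuclease-hypersensitive regions.

## Coordinate conventions

All public coordinates are 1-based and inclusive, matching the TRP1ARS1
numbering where position 1 is the first adenosine of the EcoRI site;
conversion to 0-based half-open intervals happens only inside the
bedGraph/BED writers. On a circular map position `length + 1` wraps to 1
(`wrap_pos()`), and all distances are directional: `circular_distance()`
counts clockwise (increasing-coordinate) single-base steps, with
`"shortest"` taking the smaller arc.

Three span conventions coexist because gel work uses them side by side
(`span_length()`):

* **strict_between** (`d − 1`): bases strictly between two flanking cut
  coordinates — the convention for MNase-protected lengths. The cuts at
  1,077/1,187 flanking nucleosome II give 109 bp.
* **difference** (`d`): the plain coordinate difference — used for the
  width of a chemical-signal region (1,271→1,346 gives 75 bp).
* **inclusive** (`d + 1`): both endpoints counted — used for annotated
  spans such as hypersensitive region B (1,337→62, 179 bp across the
  origin).

The published coordinates are not perfectly self-consistent about
inclusivity (the same 109-bp region is quoted with two different left
endpoints); we adopt strict-between on the cut coordinates because it
reproduces every printed length exactly.

`map_midpoint()` rounds half-integer centers toward the lower/first
coordinate. The tie rule is invisible for every printed case (1,077/1,187
has an even clockwise distance, center exactly 1,132) and only affects
unreported odd-distance spans; it is documented rather than configurable
so results are reproducible byte for byte.

Genome↔minichromosome conversion (`to_local()`, `to_genomic()`) is a
fixed offset. The minichromosome is a circularized restriction fragment,
colinear with its source locus, so a chain-file liftover machinery would
add nothing but failure modes.

## From reads to cleavage tracks

`five_prime_track()` counts read 5′ ends per base and strand (a
plus-strand read at its leftmost position; a minus-strand read at its
rightmost aligned base). `to_cleavage_sites()` shifts that mass one base
*upstream in the read's own orientation*: plus-strand mass at `p` moves
to `p − 1`, minus-strand mass to `p + 1`. The chemistry motivates the
rule — a hydroxyl-radical scission removes a nucleotide, and the
recovered fragment's 5′ end sits one base to its own 3′ side of the
broken bond on each strand. Published descriptions state the shift
without spelling out the minus-strand direction, so the convention is
isolated in this single function and can be flipped in one place if a
different chemistry demands it.

Replicates are combined by summation (`combine_tracks()`), strands by
addition (`combine_strands()`), and tracks are smoothed with a centered
moving average (`moving_average()`, default 7 bp) that wraps on circular
maps (conserving total mass exactly) and shrinks at linear edges.
`occupancy_track()` reproduces extension-style pileups: each read covers
`extsize` bases from its 5′ end in its own 3′ direction — 100 bp to
emphasize centers, 147 bp for core-particle occupancy; `extsize = 1`
degenerates to the 5′-end pileup. Reads come from a minimal SAM subset
(strand from FLAG 0/16, length from reference-consuming CIGAR operations
when present, else SEQ) or a 4-column table; output goes to
variableStep wiggle and run-merged bedGraph, both read back losslessly.

## Gel densitometry to base coordinates

`detect_bands()` finds local maxima of the (optionally 3-sample
median-smoothed) trace filtered by topographic prominence relative to
the trace maximum, with greedy thinning under a minimum separation.
Band center = position of the maximum (plateaus take their middle
sample); an intensity-centroid mode exists for symmetric, well-resolved
bands. How band centers were estimated on the original agarose gels is
not recorded — visual assignment, most likely — so the maximum is our
default: it is robust to the asymmetric tails agarose lanes develop.
Baseline subtraction (rolling minimum) is available but off by default,
since raw profiles are what gets compared in this workflow.

The size standard is piecewise-linear in `log10(size)` versus migration
(`fit_size_curve()`), the classic semi-log gel behavior; no functional
form is claimed beyond interpolation between flanking markers, and
queries beyond the outermost markers extend the terminal segment but are
always flagged `extrapolated`. Base-coordinate calibration
(`calibrate_bases()`) interpolates linearly between manually assigned
anchor bands and reproduces anchor bases exactly at anchor migrations;
orientation (whether increasing migration means increasing or decreasing
base) is inferred from the anchors, never assumed.

Primer-extension products carry one extra untemplated 3′ nucleotide (Taq
terminal transferase activity), so they run one base long relative to
dideoxy-terminated ladder controls; `apply_taq_correction()` subtracts
that base for primer-extension lanes only. Whether the correction was
ever applied to indirect-end-label agarose positions is unknowable from
the published record; we do not apply it there, since the correction is
described only for primer extension and agarose resolution makes ±1 bp
meaningless anyway. `trace_to_base_grid()` then bins calibrated samples
into per-base means (`[b − 0.5, b + 0.5)`), fills empty interior bases
by linear interpolation, and `correlate_with_track()` compares the
result against a cleavage track (Pearson plus Spearman; zero-variance
windows report `NA` rather than erroring).

## Nucleosome inference

`find_protected_regions()` compares a naked digest with a chromatin
digest, both normalized to their own totals so digestion depth cancels.
A naked cut site is *suppressed* when no chromatin site within
`match_tol` (default ±3 bp — gel bands and pileup positions never
coincide exactly) carries at least `suppression_ratio` (default 0.5) of
its normalized intensity. Intensities enter this comparison at *band
resolution*: a site's effective intensity is its set's summed mass
within ±`match_tol`. This choice matters. With raw per-position
multiplicities, a stray chromatin cut of count 2–3 inside a footprint
can "rescue" a weak naked site and split the region — at 5,000 cuts on a
500-bp circle that happens two or three times per realization. A gel
band integrates signal over exactly this kind of resolution window, so
band-scale comparison is both the physically faithful reading and the
stable one. Regions are then the gaps between consecutive *eligible*
bounding cuts — chromatin cuts at positions whose nearby naked signal is
not suppressed — that contain a run of at least `min_suppressed`
consecutive suppressed naked sites. Weak intra-footprint chromatin cuts
are ineligible as bounds, and regions are disjoint by construction.

`chemical_center()` returns the intensity-weighted centroid of chemical
signal in a window, computed by unwrapping positions along the clockwise
arc so origin-spanning nucleosomes (nucleosome IV, dyad 104 on
TRP1ARS1) are handled exactly; rounding is to the nearest base with
half-integer ties toward the lower coordinate, and an `argmax` mode
exists for single-band calls. `center_offset()` is the signed shortest
circular distance (clockwise positive — an arbitrary but fixed
orientation) between chemical center and MNase midpoint.

`classify_call()` applies the two thresholds that matter and exposes
both as parameters: protection wider than 150 bp makes the midpoint an
unreliable center estimate (`wide_protection`, since the region exceeds
a core particle the octamer may sit off-center in it); otherwise offsets
within 20 bp are `consistent` and larger ones `shifted`. A protection of
at most `core_len − 15` bp (132 bp for canonical cores) is additionally
flagged `short_protection` — the signature of a nucleosome whose flank
is invaded by a nuclease-sensitive region. The flag is a separate field
rather than a class because short protection co-occurs with either
offset class.

`nfr_size()` converts two dyads into a nucleosome-free-region size:
clockwise center-to-center distance minus one core length, floored at
zero. With the mapped dyads 1,308 and 104 and a canonical 147-bp core
the gap is 102 bp; the literature rounds this figure to "about 105 bp",
which no integer core length in 145–147 reproduces exactly (those give
102–104 bp). We keep the arithmetic honest, default `core_len = 147`,
and note the ~3-bp discrepancy as a rounding artifact of the original
report rather than tuning the core length to hit it.

`enumerate_frames()` returns *all* cut pairs whose strict-between width
lies within `target_width ± tol` — overlapping frames are the point, as
multiple compatible windows of core-particle width are the signature of
redundant, alternative nucleosome positioning. Slash-separated
alternative cut readings from the original gels (e.g. 1,264/1,271) are
treated as independent cuts, so supersets of the annotated brackets can
appear; they are genuine width-compatible pairs.

## What the simulators emulate — and what they do not

`simulate_chemical_reads()` places each read so that pileup → 1-bp
upstream shift recovers a cleavage at `dyad + offset` on the drawn
strand; offsets come from a per-strand `chemical_offset_model()`. The
default is symmetric, identical on both strands: offsets −2…+2 with
probabilities 0.15/0.2/0.3/0.2/0.15. The real S47C chemistry cleaves
with strand-specific patterns whose exact offsets are not published for
this assay, so the default encodes only "near the center, a couple of
bases of spread" and makes no claim about the true per-strand geometry;
strand-asymmetric tables plug straight in.

`simulate_mnase_cuts()` draws cut positions from per-base weights:
uniform for naked DNA, and `linker_cut_weight = 1` versus
`core_cut_weight = 0.02` (cores = dyad ± 73 bp) for chromatin — a ~50×
linker preference, the order of magnitude a limited digest of a
positioned array shows. An optional A/T preference multiplies the weight
where the base 5′ of the cut is A or T, when sequence is supplied; a
geometric end-trimming model for MNase's exonuclease activity was
considered and left out of the defaults, as none of the recovery
analyses depend on fragment ends. `simulate_gel_lane()` renders
fragments as abundance-scaled Gaussian bands on the semi-log migration
model plus optional white noise, emitting the matching marker-lane
standard and true band centers.

What the simulators deliberately do **not** model: sequencing
library-prep biases (end repair, ligation, size selection, PCR),
MNase's processive end-trimming, nucleosome breathing or partial
unwrapping, and sequence-dependent nucleosome affinity. Passing recovery
tests therefore demonstrates that the *analysis* is unbiased and
correctly handles circular topology — not that real chromatin data are
free of these upstream biases.

All generators take a mandatory seed, draw inside a local RNG scope
(the caller's random stream is untouched), and are bit-reproducible; a
frozen fingerprint in the test suite guards the stream against silent
regressions.

## Problem sizes and numerical choices

The bundled analyses and tests use the scales at which the statistical
guarantees hold comfortably: 2,000 chemical reads per nucleosome for
center recovery (median error ≤ 1 bp, max ≤ 3 bp over 100 random
dyads), 5,000 MNase cuts per substrate for footprint recovery (midpoint
within ±5 bp of the dyad), 20,000–60,000 draws for distributional
checks, and 200 random read sets for exact oracle equivalence of the
pileup code. Band detection on synthetic lanes recovers marker sizes
within 3% over 100–2,000 bp at zero noise; since the forward model and
the calibration are both log-linear, residual error is sampling
discretization only.

Degenerate inputs are handled explicitly: flat traces yield zero bands
(not an error); zero signal inside a valid window is an error distinct
from a window containing no positions; empty chromatin cut sets are an
error (no bounding cuts can exist); strict-between spans of adjacent or
identical cuts are 0, never negative; even smoothing windows are
rejected rather than silently recentered.

## Limitations

* The package analyzes one reference at a time; multi-chromosome genome
  models, chain-file liftover and alignment-gap-aware conversion are out
  of scope.
* It starts from extracted 1-D lane traces; 2-D gel image processing
  (lane finding, image background) is upstream of this package.
* Nucleosome calling is deterministic interval arithmetic on cut sets —
  there is no statistical occupancy model, no genome-wide peak calling,
  and no subnucleosome/hexasome fitting.
* The chemical offset model is a configurable stand-in; inferences that
  depend on the true strand-specific S47C cleavage geometry should
  calibrate it against data rather than rely on the default.
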