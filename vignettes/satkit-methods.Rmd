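---
title: "satkit: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{satkit: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the science inside `satkit`: the models each stage
assumes, the parameters that matter and their defaults, the places where a
published workflow leaves a rule underspecified and the choice this package
makes there, and what validation on synthetic data does and does not show
about real assemblies.

## 1. Monomer annotation

### Model

A satDNA family is represented by one consensus monomer. A genomic segment
is a monomer copy when it aligns end-to-end to *some rotation* of the
consensus, on either strand, with divergence at most `max_divergence`
(default 0.45). Rotation matters because tandem arrays have no canonical
phase: a copy may begin at any offset of the repeat unit.

Divergence at this stage is **alignment distance** — mismatches over the
monomer length — not an evolutionary distance. The 45% ceiling is a
similarity screen for calling copies; the substitution-corrected K2P value
is computed separately by the divergence stage. The two scales differ
materially: a K2P distance of 0.60 corresponds to an expected raw mismatch
fraction of only ~0.40, still inside a 45% screen. `N` counts as a mismatch,
conservatively toward the ceiling.

### Algorithm

The search is an exhaustive ungapped wraparound scan. A copy starting at
position $s$ with rotation $r$ reads consensus index $(x - d) \bmod L$ at
genome position $x$, where $d = (s - r) \bmod L$ is the copy's *diagonal*.
For each of the $L$ diagonals the per-base mismatch indicator is computed
and a window of one monomer length slides along the chromosome (implemented
in C++; $O(GL)$ per family and strand). Every window within the ceiling is
a candidate, so on substitution-only ground truth recall inside the ceiling
is exhaustive by construction. Both strands are scanned by repeating the
procedure on the reverse complement.

Candidates on one diagonal are clustered into array regions. Region
boundaries are refined by a change-point criterion: walking outward from an
anchor window, the cumulative sum of (match − ½) rises inside the array
(match rate ≥ 0.55 at the ceiling, ≥ 0.7 in realistic regimes) and falls in
background (rate ¼); the boundary is where the sum peaks, required to clear
a margin of 3 (six net matching bases) so that short chance runs of
background matches do not drag the boundary outward. Monomers are then tiled
from the boundary at consensus-length periodicity — tiling, rather than
per-monomer re-seeding, prevents boundary jitter accumulating inside long
arrays. Because a mutation clump at an array edge can stall one change-point
a fraction of a monomer short, the grid is anchored at whichever refined
boundary yields the lower total mismatch count (ties go left).

**Inherent boundary ambiguity.** When the background base adjacent to an
array happens to continue the periodic pattern, the extended annotation is
*exactly as good* as the true one — for a divergence-0 array, both tilings
have divergence 0. No algorithm can resolve this from sequence alone, so
array starts carry a few-bp ambiguity with probability ~¼ per edge. Tests
and downstream analyses treat boundaries accordingly (reciprocal-overlap
matching; alignment-based flank comparison).

Overlaps within a family are resolved greedily by ascending divergence,
ties by leftmost start, then + strand: deterministic and favouring the best
copies. Note this tie-break is orientation-dependent, so annotating a
reverse-complemented assembly mirrors coordinates only up to the same
few-bp ambiguity.

**Background false positives and monomer length.** Under a uniform random
background the mismatch count of a window is Binomial($L$, 0.75), so the
probability of slipping under the 45% ceiling is a steep function of $L$:
negligible at 142 bp, ~$10^{-7}$ per window-diagonal at 60 bp (about one
spurious monomer per few Mb scanned), and substantial below 40 bp. This is
a property of the screen itself, not of the implementation; analyses of
very short repeat units should lower the ceiling.

### Arrays

Maximal runs of same-family, same-strand hits with inter-hit gaps at most
`gap_tolerance` become arrays. The default tolerance is one monomer length:
a single lost or fully degenerate monomer should not split an array, while
unrelated arrays (in simulation: separated by at least `min_gap` = 500 bp)
never merge. The tolerance is configurable and logged; there is no
community-standard definition of "one array".

## 2. Divergence landscapes and peak calling

Each monomer is compared to the consensus rotated by its reported rotation
(position-wise, since the annotator is ungapped; length-discrepant input is
globally aligned first with match +1 / mismatch −1 / gap open −2 /
extend −1 — one alignment policy package-wide). The Kimura 2-parameter
distance is

$$ d = -\tfrac12 \ln\!\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right] $$

with $P$, $Q$ the transition and transversion proportions over ungapped,
unambiguous columns. Saturated pairs (log argument ≤ 0) are flagged
infinite and excluded from landscapes with a logged count. Finite distances
are binned at `bin_width` = 0.01 (bin $k$ covers $[k w, (k+1) w)$);
abundance is monomer count by default, with a bp-weighted mode available,
as the published landscape convention does not state units.

### The peak rule

The qualitative rule — "a bin or series of neighboring bins 50% higher than
the preceding and following bins" — is underspecified in ways that only
surface on real histograms. The package provides two callers.

`call_peaks` is the literal run rule made coherent. A peak is a maximal
run of bins in which every bin (or, behind a flag, the run maximum) is at
least `peak_factor` times both bins adjacent to the run, with three
necessary refinements:

1. **Edges.** Out-of-range neighbours count as 0, making edge conditions
   one-sided. Taken alone this would let the entire landscape qualify
   vacuously, so in addition **at least one neighbouring bin must be
   positive**: "50% higher" must be demonstrated against real abundance.
   This also stops an isolated bin bordered by empty bins from counting as
   a peak.
2. **Internal valleys.** The neighbour comparison never looks inside a run,
   so two modes bridged by low but non-zero bins would merge into a single
   qualifying run. A run is therefore **admissible** only if it contains no
   internal valley whose flanking run-maxima both strictly exceed it and
   reach `peak_factor` times its value; such a valley separates two peaks.
   A shallow dip (as in the landscape `[10, 9, 10, 1, 1]`, where
   $10 < 1.5 \times 9$) does *not* split: the run `[10,9,10]` is one peak.
3. **Every bin vs run maximum.** The default is the literal "every bin"
   reading, with the `run_max` alternative behind a flag.

Peaks are the maximal admissible qualifying runs, left to right, overlaps
resolved leftmost-first. `call_peaks` is verified against an independent
exhaustive run-enumeration oracle over the full grid of length-8
landscapes with values in {0,1,2,3}.

Even with the valley condition, the literal rule has a structural blind
spot on smooth count histograms: a genuine secondary mode only qualifies if
some cut point clears the 1.5× bar against *both* of its immediate
neighbours simultaneously, and Poisson noise in the two tails denies such a
cut in a substantial minority of genuinely bimodal landscapes (about 15% at
5,000 monomers in the validation mixtures). `call_peaks_prominence` is the
formalisation of the same idea that does not depend on single-bin cuts:
local-maximum plateaus are candidate peaks, two adjacent candidates merge
whenever the smaller apex is below `peak_factor` times the saddle between
them (they are then "a series of neighboring bins" acting as one peak), and
each surviving group's run is the contiguous `apex / peak_factor` contour
around its apex — which by construction puts the bins just outside the run
below apex/1.5, so the "50% higher" comparison holds. Both callers agree on
the worked examples above; they differ exactly on noisy multi-modal
histograms, where the prominence caller recovers the planted modes in
150/150 validation replicates versus ~85% for the literal rule.

`classify_landscape` labels a peak set as unimodal-low (single peak, apex
below 10% divergence), unimodal-shifted, bimodal or multimodal, and
`family_landscape` feeds it the prominence caller's peaks. Both callers
take an apex floor (`min_fraction`, default 1% of total abundance in the
classification path): in a count histogram of a few thousand monomers the
sampling tail contains bins of 1–5 counts that formally qualify under any
threshold rule; a 1% floor (≥ 50 monomers at $n = 5000$) separates them
cleanly from genuine secondary modes, which carry hundreds of monomers.
Shape classification is meaningful from roughly a thousand monomers upward;
for small families the label reflects sampling noise.

For estimating a mode's position, the peak table's abundance-weighted basin
**centroid** (continuous, in bin coordinates) is the statistic to use: the
argmax bin of a broad mode jitters by ±2–3 bins under count noise, while
the centroid is a mean with negligible standard error and recovers planted
mixture means within one bin width throughout the validations.

## 3. Flank conservation

`extract_flanks` returns `flank_length` (default 1,000) bp upstream and
downstream of each array, oriented 5'→3' on the array strand (minus-strand
arrays swap sides and reverse-complement), flagging contig-edge truncation.

`conservation_profile` aligns each member to a deterministic reference
flank and measures, in 100-bp windows walking away from the array boundary,
the fraction of members with ≥ `identity_threshold` (default 0.95) windowed
identity. The conserved block length is the largest $L$ such that every
window inside $[0, L)$ keeps ≥ `member_fraction` (default 0.75) of members
above threshold — defaults consistent with reported >95%/>99% conserved
stretches while tolerating a minority of aberrant members.

The reference is the member of *modal* length (ties: longer, then source
coordinate). Choosing the longest member outright fails exactly when it
matters: an insertion-bearing member would become the yardstick and destroy
the block for everyone else. Outlier members inside the block are
classified as **truncation** (flagged or short), **insertion** (similarity
to the reference resumes at a positional offset ≥ `min_insertion` past the
failure point — detected on the shifted diagonal directly, because mild gap
penalties fragment a long insertion into uninformative micro-gaps), or
**early similarity loss** otherwise.

## 4. Transcription quantification

Reads are counted against each family's head-to-tail **dimer** (consensus
twice), so reads spanning the junction between monomer copies align
end-to-end without clipping. A read counts for a family when it matches
some offset of the dimer, either strand, ungapped, with at most
`mismatch_limit` (default 1) mismatches; base qualities are ignored (the
criterion is mismatch count). A read may count for several families
(all-alignments semantics) but once per family; paired fragments count once
if either mate matches. At a one-mismatch ceiling over a dimer reference,
gapped alignments are outside the acceptance region, which is why an
explicit ungapped matcher — exhaustively verifiable against a brute-force
oracle — is used instead of a heuristic mapper.

FPKM is $C_s \cdot 10^9 / (L_s N)$ with $L_s$ the dimer length and $N$ the
library-size denominator — total fragments by default, or genome-mapped
fragments when an external mapping supplies them (the published choice of
denominator is unstated; both are supported). Because copy number differs
enormously between families, FPKM is valid **longitudinally only** — one
family across stages and sexes — never for ranking families;
`expression_profile` aggregates mean, sd and replicate count per family ×
stage × sex, and a simple minimum-depth filter stands in for full library
QC (out of scope here).

## 5. Phylogeny and minimal age

Per family, up to `subsample_n` = 100 monomers are uniformly subsampled
(deterministic under seed). Equal-length monomer sets (the annotator's
output is already in consensus coordinates; externally collected monomers
need an MSA first, which is out of scope) yield a pairwise K2P matrix;
members of saturated pairs are dropped greedily with a log. Trees are built
by neighbor-joining — implemented in the package, not delegated, because NJ
admits exact verification: on additive matrices the output tree's
path-length matrix reproduces the input to machine precision, which the
tests exercise against random trees and against an established independent
implementation. Bootstrap supports resample alignment columns with
replacement, rebuild distance+NJ trees, and report the fraction of
replicates containing each original bipartition (default 100 replicates).

Taxonomic presence uses a strict filter: a taxon qualifies for a family
only when its best query coverage *exceeds* 0.5 of the monomer ("exceeded"
read literally; a coverage of exactly 0.50 is absence). A rank-collapse
step maps species-level hits to orders (one qualifying species suffices for
its order), keeping the age operation rank-agnostic.

The **minimal age** of a family is the age of the MRCA of the focal taxon
and all qualifying taxa on a time-calibrated tree: the family must already
have existed when those lineages separated. This equals the maximum
pairwise divergence time among qualifying taxa — the brute-force oracle
used in the tests. Node ages come from an ultrametric Newick's branch
lengths (leaf-depth spread beyond tolerance is an error) or from
internal-node labels, declared explicitly. A family detected only in the
focal taxon gives no MRCA bound; its age is reported as the interval
[0, `clade_bound`], the bound being the dated emergence of the focal
taxon's family-level clade, supplied from configuration. Ages are reported
verbatim from the input tree — the package does not re-round them.

The bundled `insect_orders_timetree.nwk` encodes the order-level dated tree
used in the worked examples (splits at 380, 360, 340 MY; the internal
Coleoptera/(Lepidoptera, Diptera) ages of 327/290 MY are TTOL-typical
values that no result depends on).

## 6. Synthetic data: what it emulates and what it does not

### Mutation model

`mutate_monomer` applies the two-rate substitution process at branch length
equal to the target divergence: with `kappa` the expected
transition:transversion *count* ratio (default 2, i.e. two thirds of
substitutions are transitions), per-site category probabilities are the K80
transition probabilities at that distance. Plugging the expected
proportions into the K2P formula returns the target exactly, so the
generator is unbiased for the estimator it feeds (verified by Monte Carlo:
mean measured K2P within [0.095, 0.105] at target 0.10 over 10,000
replicates). Targets ≥ 0.75 are rejected — the K2P transform saturates.
Substitution only by default: the divergence ceiling and the K2P estimator
are defined over substitutions; indel robustness is a separate concern and
is not claimed by these tests.

### Genome, reads, presence

Planted genomes draw i.i.d. uniform background (the simplest null that
cannot systematically mimic consensus k-mers), place arrays by rejection
sampling with a 500-bp minimum separation (comfortably above the
array-merging tolerance for typical monomer lengths), give every array a
random rotation and strand, and draw per-monomer divergences from a
truncated-normal mixture (component sd 0.01 unless specified — tight
enough that landscape modes reflect the means). Organisation modes mirror
the classes seen in real satellitomes: interspersed (round-robin over
shuffled chromosomes — guarantees breadth without terminal bias), terminal
blocks (placed within 4% of chromosome ends, inside the 5% window the
classifier uses), single block, and chromosome-restricted.

Read simulation draws satellite fragments uniformly from all end-to-end
dimer offsets on both strands (so a known fraction spans the monomer
junction), applies a uniform per-base substitution error (default 0.002, a
conventional short-read figure), and adds uniform-random background reads.
With a one-mismatch counting ceiling, the expected loss is the binomial
two-error probability $1-(1-p)^{\ell}-\ell p(1-p)^{\ell-1}$, which the
closure tests verify within Monte-Carlo error.

Presence simulation plants an MRCA node per family on the focal taxon's
root path and samples qualifying taxa so the MRCA is pinned exactly (one
anchor leaf from a non-focal child subtree, plus random extras below the
node); coverages straddle the 0.5 threshold strictly.

**Limitations.** Real assemblies contain transposable elements and
low-complexity tracts that inflate spurious similarity relative to the
uniform null; real satDNA arrays carry indels and higher-order repeat
structure that the substitution-only simulator does not generate (the
annotator is ungapped — indel-rich families would fragment into shorter
hits); real libraries have positional error profiles, adapter residues and
coverage biases; and assembly collapse systematically *removes* high-copy
satDNA, so counts measured on an assembly bound the genomic truth from
below. Passing the synthetic validations therefore demonstrates
correctness of the computations under the stated models, not fidelity of
any particular assembly's satellitome.

## 7. Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally everywhere; conversion
  happens only in the GFF3 writer (1-based inclusive) — one convention, no
  off-by-one drift. BED carries divergence × 1000 in the score column.
* Ambiguity codes other than N are rejected at parse time, with an opt-in
  coercion to N; divergence arithmetic is defined over {A,C,G,T}.
* Empty genomes, empty hit tables and all-zero landscapes return typed
  empty results (with warnings where the input is suspicious), not errors;
  a single flank, an all-saturated distance matrix, a zero-fragment
  library and a qualifying taxon missing from the dated tree are errors.
* NJ ties (equal Q-criterion) break row-major; star-like matrices yield
  zero-length internal branches and a log message.
* All stochastic components take explicit seeds and restore the caller's
  RNG state; fixed seed implies byte-identical output, manifest included
  (`run_pipeline` records config, seed, versions and output digests).

## 8. Validation scale

The stochastic validations run at the following sizes, chosen to give
stable statistics at interactive runtimes: annotator recovery on a 2-Mb
genome with ~2,300 planted monomers across four families and three
organisation classes (recall and precision ≥ 0.995 at 90% reciprocal
overlap); landscape shape recovery over 50 seeded replicates × 3 mixtures
× 5,000 monomers; transcription closure at 16 libraries × 1,200–6,000
fragments plus a 10,000-read error-loss check; peak-caller equivalence
over all 65,536 length-8 value-grid landscapes; NJ inversion on additive
matrices of 4–8 taxa; and 20 random planted-MRCA recoveries on random
dated trees.
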