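# satkit

Satellite DNAs (satDNAs) are tandemly repeated sequences organised in arrays
of head-to-tail monomers, concentrated in (peri)centromeric and subtelomeric
heterochromatin but also scattered through euchromatin as short arrays.
Characterising a species' full satDNA complement — its *satellitome* — means
answering, for every family, the same set of questions: where do its monomers
sit on the assembly and how are they organised; how diverged are the copies
from the family consensus and what does the shape of that divergence
distribution say about amplification history; what flanks the arrays; is the
family transcribed, when, and in which sex; and how old is it, judged by which
taxa share it on a dated phylogeny.

`satkit` is an R package that implements this whole workflow for assemblies
at desk scale, together with simulators that generate synthetic satellitomes
with known ground truth so that every stage can be validated end to end
without downloading anything. It is aimed at researchers doing repeat biology
on emerging model species — the kind of project where the satellitome is
annotated from a handful of consensus sequences against a chromosome-level
assembly.

## What it computes

* **Annotation** — every monomer copy of each family on the assembly, at up
  to 45% divergence from the consensus, on either strand and at any rotation
  (tandem monomers have no canonical phase). The search is an exhaustive
  ungapped wraparound scan; monomers are merged into arrays by a gap
  tolerance of one monomer length, and a per-family summary (counts,
  chromosome distribution, genome fraction) reproduces the usual satellitome
  table.
* **Divergence landscapes** — Kimura 2-parameter distance of every monomer
  from its consensus,
  `d = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]`
  with `P`/`Q` the transition/transversion proportions, binned at 1%.
  Peaks are called by a rule-based caller (a run of bins 50% higher than its
  neighbours, with internal valleys splitting runs) and landscapes are
  classified as unimodal-low, unimodal-shifted, bimodal or multimodal.
* **Flanks** — 1,000 bp upstream/downstream of each array, strand-oriented,
  with a windowed conservation profile that measures how far from the array
  boundary the flanks stay similar, and classifies outlier members
  (insertion / truncation / early similarity loss).
* **Transcription** — reads are counted against each family's head-to-tail
  dimer reference (so junction-spanning reads align end-to-end) with at most
  one mismatch, then FPKM-normalised: `FPKM = C_s 1e9 / (L_s N)`. FPKM here
  is valid longitudinally (one family across stages/sexes), never across
  families.
* **Phylogeny and age** — monomer subsampling (100 per family), K2P distance
  matrices, neighbor-joining trees with column-bootstrap supports, a strict
  query-coverage filter (> 50% of the monomer) for taxonomic presence, and
  the minimal age of a family as the age of the MRCA of all taxa sharing it
  on a time-calibrated tree.
* **Simulators** — genomes with planted arrays (interspersed / terminal
  blocks / single block / chromosome-restricted, with divergence mixtures,
  random rotations and optional flanking cassettes), stage-and-sex
  structured read sets, and presence matrices with a planted MRCA — each
  with machine-readable truth tables.

## Worked example

```r
library(satkit)

## a 142-bp family planted on a toy genome, then re-annotated
set.seed(1)
fam  <- sat_family("TmSat01", paste(sample(c("A","C","G","T"), 142, TRUE), collapse = ""))
spec <- family_sim_spec(fam, "interspersed", n_arrays = 12,
                        array_length_range = c(2, 6),
                        divergence_mixture = data.frame(weight = 1, mean = 0.10, sd = 0.01))
sim  <- simulate_genome(list(spec), c(chr1 = 50000, chr2 = 50000, chr3 = 50000), seed = 7)
hits <- find_monomers(sim$genome, fam, max_divergence = 0.45)
nrow(hits); nrow(sim$truth)
#> [1] 47
#> [1] 47
arrays <- build_arrays(hits)
nrow(arrays)
#> [1] 12

## divergence landscape: shape classification needs abundance, so profile a
## denser planting of the same family
dense <- family_sim_spec(fam, "restricted_chromosome", n_arrays = 150,
                         array_length_range = c(6, 10),
                         divergence_mixture = data.frame(weight = 1, mean = 0.10, sd = 0.01))
sim2  <- simulate_genome(list(dense), c(chr1 = 1500000), seed = 8, min_gap = 300)
hits2 <- find_monomers(sim2$genome, fam, 0.45)
fl <- family_landscape(hits2, sim2$genome, fam)
fl$shape
#> [1] "unimodal_low"
fl$peaks
#>   from to apex_bin apex_value basin_from basin_to centroid
#> 1    9  9        9        241          0       20 10.03697

## minimal age on the insect-order timetree
tr   <- read_newick_dated(system.file("extdata", "insect_orders_timetree.nwk",
                                      package = "satkit"))
pres <- filter_presence(data.frame(taxon = c("Lepidoptera", "Hymenoptera", "Blattodea"),
                                   family = "TmSat01", query_coverage = 0.9),
                        focal_taxon = "Coleoptera")
minimal_age(pres, tr, "TmSat01", "Coleoptera")$minimal_age
#> [1] 380
```

All 47 planted monomers come back (the annotator's recall on
substitution-only truth inside the divergence ceiling is exhaustive by
construction), grouped into exactly the 12 planted arrays. The dense
planting's landscape has a single low-divergence peak whose apex sits in
the 9--10% bin and whose abundance-weighted centroid (10.04 in bin
coordinates, i.e. ~10.0% divergence) recovers the planted 10% mixture
mean. And a family shared by Coleoptera, Lepidoptera, Hymenoptera and
Blattodea must predate their separation 380 million years ago.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/satkit.R` (subcommands `annotate`, `landscape`, `quantify`,
`age`).

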