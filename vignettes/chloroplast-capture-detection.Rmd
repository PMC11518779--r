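---
title: "Detecting chloroplast capture from cyto-nuclear discordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chloroplast capture from cyto-nuclear discordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpcapture)
```

## The problem

Plastomes are uniparentally inherited and effectively non-recombining, so a
chloroplast phylogeny traces a single maternal genealogy. When hybridization
followed by backcrossing replaces one species' plastome with another's
("chloroplast capture"), the chloroplast tree and the nuclear tree disagree:
nuclear data show clean species clades while plastome clades mix accessions
of several species, typically grouped by geography rather than by taxonomy.
`cpcapture` implements a desk-scale version of a workflow for wild tree-crop
populations of four closely related species plus an outgroup: build the
nuclear species phylogeny from single-copy genes, build the plastome
phylogeny, and quantify where and how strongly the two disagree.

Every stage is exercised against a synthetic data generator with known ground
truth, so the whole chain — gene selection, variant filtering, consensus
reconstruction, tree building, discordance statistics — is testable
end-to-end.

## The synthetic study system

`simulation_config()` fixes the study conditions. Four ingroup species sit on
the topology `((S1,S2),(S3,S4))` with an outgroup at the root — the shape in
which two larger species form one clade and two smaller species its sister.
Defaults, with units:

* **Nuclear genes**: 53 single-copy coding genes of 501 bp (a multiple of 3,
  so every gene translates cleanly; the panel size matches the typical yield
  of single-copy screens against a congeneric reference). Branch lengths in
  substitutions/site: species tip 0.01, internal edges 0.005, outgroup 0.06,
  within-species accession branches 0.001. These give roughly 91% identical
  columns against the outgroup on the concatenated matrix, the ballpark for
  congeneric nuclear CDS.
* **Diploidy**: each accession carries two haplotypes; beyond the shared
  accession branch, sites are heterozygous with probability `het_rate` =
  0.002.
* **Plastome**: a 20 kb proxy sequence (a scaled stand-in for a ~160 kb
  plastome; length only scales the number of informative sites). Species-level
  divergence 0.01 subs/site, within-species haplotype founders at 0.001, and
  per-accession private mutations at one fifth of that. Three haplotype
  founders per species are assigned to geographically contiguous blocks of
  collection sites, which is what gives the plastome its phylogeographic
  signal.
* **Capture events**: `n_capture_events` accessions have their plastome
  replaced by a lineage captured from the geographically nearest other
  species. Each event copies the pre-capture plastome of a specific donor
  accession (the nearest one; distinct donors across events, because separate
  events are separate hybridizations) and then accumulates post-capture
  divergence equal to three within-species founder depths — capture is an
  older event than the sampled generation, so a captured lineage is
  recognisably inside the donor's radiation without being identical to any
  extant donor. This matters for the k-nearest-neighbour detector below: if
  captured plastomes were byte copies of donor plastomes, donor accessions'
  own neighbourhoods would fill up with foreign labels and the detector would
  rightly flag them — a property of the data, not a detector bug.
* **Sequencing**: per-site depth is Poisson with mean 25x; each read comes
  from either haplotype with probability 1/2 and is miscalled to a uniformly
  random other base with probability 0.001. An optional per-accession
  `depth_range` reproduces the 16–44x spread seen in real short-read sets;
  it is off by default so the stated Poisson(25) model holds exactly. The
  choice of Poisson is ours: real pipelines report per-sample depth ranges,
  not per-site distributions.
* The outgroup contributes reference-quality sequences directly (no pileups),
  mirroring workflows in which the outgroup is a finished assembly rather
  than a resequenced sample.

What the generator deliberately does **not** emulate: incomplete lineage
sorting (within-species structure is shallow, so an ILS knob would add
machinery without adding signal), indels and alignment error (all sequences
stay in reference coordinates; the real workflow's alignment step is
trivialised by construction), read-level artefacts (mapping bias, base
quality), and plastome structural variation. Passing tests therefore show
that the statistics recover a clean capture signal at realistic divergences —
not that they are robust to misalignment or ILS-driven discordance, which on
real data must be weighed separately (the package reports parsimony excess
and support values and leaves that interpretation to the user).

## Single-copy gene selection

Queries (translated panel CDS) are aligned to every reference CDS database
with local Smith–Waterman over all three forward frame translations (BLOSUM62,
affine gaps open 11 / extend 1 — the classic translated-search scoring).
A gene is kept only if it has exactly **one** distinct subject above
`min_score` in **every** database; "single hit" counts subjects, not
alignment fragments. The acceptance threshold is a raw score of 70 (~31 bits
via the Karlin–Altschul conversion with lambda = 0.267, K = 0.041, available
as `bit_score()`): random local alignments between unrelated proteins of a
few hundred residues reach the low 50s, so a threshold of 70 sits above the
noise floor while any true ortholog at these divergences scores in the
hundreds. Reverse-strand frames are off by default because CDS databases are
stranded. External search output can be substituted via
`import_tabular_hits()` (12-column tabular format).

## Variant filtering and consensus reconstruction

`call_site()` is the fixed-ploidy rule set: a site needs depth >= 10;
candidate alleles need count >= 3 and frequency >= 25%; a heterozygous call
requires exactly two candidates, both within 25–75%; a homozygous call
requires one candidate, different from the reference, at 100% frequency.
Everything else — including sites with three or more candidates, which cannot
be diploid genotypes — is a no-call. `hom_min = 1.0` is the literal default;
with non-zero sequencing error a literal 100% discards most true homozygous
variants, so `caller_config(hom_min = 0.97)` is the documented setting for
noisy data. Frequencies are raw count fractions (no base-quality weighting).

One statistical consequence worth knowing: with reads split
Binomial(depth, 1/2) between haplotypes, a true heterozygous site at 25x
falls outside the 25–75% band about 1.5% of the time and is then filtered.
The reconstruction consequently reverts such sites to the reference base.
This is inherent to the frequency-band filter at finite depth, not an
implementation artefact; the test suite pins down that **every** round-trip
miss is exactly such a band-tail site and that homozygous genotypes are
always recovered at covered sites.

`apply_variants()` writes homozygous alleles directly and encodes
heterozygous calls as IUPAC ambiguity codes (A/G→R and so on), preserving
both alleles for downstream distance and likelihood computations; a
`haploidize = "major"` option exists for sensitivity analysis. No-call sites
inherit the reference base (consensus semantics); masking them to N is
available but off by default. `build_supermatrix()` concatenates genes in
fixed panel order — the column order is part of the contract — and records
0-based half-open gene blocks (positions are 1-based only in the variant CSV
and pileup TSV, converting at the I/O boundary).

## Trees

Distances: the raw statistic is mean per-site mismatch, with an ambiguity
code contributing its expected mismatch over the code's base set (A vs R is
0.5); `JC69` applies d = -(3/4)log(1 - 4p/3) and flags p >= 0.75 as
saturated. Neighbor joining uses the Studier–Keppler Q criterion with two
deliberate determinism rules: ties in Q break lexicographically on the pair
of smallest contained leaf labels, and negative branch-length estimates are
clamped to zero with the deficit moved to the sibling edge so path lengths
are preserved. Trees serialize to a canonical Newick form (children ordered
by smallest descendant label), which makes outputs byte-stable.

Likelihood: Felsenstein pruning under JC69 with uniform base frequencies and
site-pattern compression; ambiguity codes enter as partial likelihoods. For
up to 7 leaves, `exhaustive_ml_topology()` scores all (2n-5)!! unrooted
topologies, optimizing each branch by cyclic Brent search (tolerance 1e-6,
at most 20 sweeps), and breaks exact ties by enumeration order. This is an
exact small-instance substitute for heuristic ML search; the richer models
real pipelines select (GTR+Gamma and relatives) are intentionally not
re-implemented — at the simulated divergences topology recovery is
insensitive to the model, and the package's conclusions rest on topology.

Support: nonparametric site bootstrap (seeded, deterministic), reported as
integer percentages of replicates containing each original bipartition.
Internally the distance-builder bootstrap avoids recomputing alignments: the
per-pair per-site mismatch profile is computed once and each replicate is a
weighted column average. `majority_rule_consensus()`, `robinson_foulds()`
(symmetric bipartition difference), `root_on_outgroup()` (root at the
midpoint of the outgroup's pendant edge) and `monophyly_check()` operate on
the same canonical bipartition machinery.

## Species tree by quartet concordance

With exactly four ingroup species there are three unrooted species
topologies, so the quartet-based species-tree problem is solved exhaustively:
for every gene tree, one-accession-per-species quartets (all of them, or a
seeded uniform sample above `max_combos`) are read off the tree by the
four-point condition on edge-count distances, and each resolved quartet votes
for the topology it displays. The reported support is the winning vote
fraction — explicitly **not** a local posterior probability. Exact ties are
an error rather than an arbitrary pick. Restricting to four species is a
design decision: a general dynamic-programming species-tree method would
import a large algorithm this problem does not need.

## Discordance and phylogeography

* `fitch_parsimony()` counts the minimum number of species-label transitions
  on a tree; `parsimony_excess()` subtracts the unavoidable
  (number of species - 1). Excess 0 is equivalent to every species being
  monophyletic; each independently placed captured accession adds one. Two
  caveats are documented rather than hidden: the statistic is a minimum, so
  interacting placements (e.g. reciprocal captures between species whose
  clades are adjacent) can absorb a transition and report an excess one lower
  than the event count; and it cannot by itself distinguish capture from
  incomplete lineage sorting — the package reports the statistics and support
  values and leaves that call to the user.
* `capture_candidates()` flags an accession when the majority species among
  its k = 3 patristically nearest ingroup neighbours differs from its own
  label, with ties (distance, then lexicographic id; majority ties are
  recorded as ambiguous and left unflagged) resolved conservatively. The
  margin — distance to the nearest same-species leaf minus nearest
  other-species leaf — is reported so borderline flags are visible;
  `autoplot()` draws it per accession.
* `mantel_test()` is the quantitative substitute for drawing clade-coloured
  maps: Pearson correlation between plastome patristic and Euclidean
  geographic distances, with significance from jointly permuting rows and
  columns of the second matrix and the standard one-sided estimator
  (1 + exceedances) / (n_perm + 1). The outgroup is excluded by default.
* `clade_species_composition()` tallies species on both sides of every
  supported bipartition and marks mixed clades; `haplotype_summary()` counts
  exactly distinct sequences and Hamming differences (the
  one-divergent-accession-in-an-otherwise-uniform-species pattern falls out
  of this directly).

## The pipeline

`run_pipeline(run_config(...))` chains the stages
(simulate → select → call → reconstruct → trees → species tree →
discordance), writing FASTA/Newick/TSV/CSV artefacts plus a JSON summary and
a manifest of MD5 content hashes. All randomness derives from the simulation
seed (stage-specific seeds are small fixed offsets), so a rerun with the same
configuration reproduces identical hashes; the manifest's timestamp is the
only non-reproducible field. The configuration constructors reject unknown
arguments and validate field domains, naming the offending field. The R
functions themselves are the interface; there is no shell entry point beyond
`scripts/acceptance.R`.

```{r, eval = FALSE}
cfg <- run_config(
  sim = simulation_config(seed = 1, n_capture_events = 5),
  bootstrap_B = 200)
res <- run_pipeline(cfg)
glance(res$capture_report)
tidy(res$mantel)
```

## Numerical and testing choices

Problem sizes in the test suite are chosen to keep the full suite in the
tens-of-minutes range on one core while still testing the stated study
conditions: the species-topology recovery and capture checks run the complete
default system (40 accessions + outgroup, 53 genes) over 20 fixed seeds
(1–20) with 200 bootstrap replicates; oracle-equivalence checks (caller rule
enumeration to depth 15, brute-force Fitch and likelihood summation,
independent Gotoh alignment, additive-distance NJ recovery) run at the small
sizes where exhaustive enumeration is exact. phangorn, vegan and ape serve as
independent cross-checks of likelihood, Mantel r, Robinson–Foulds and
consensus values — never as the implementation. Degenerate inputs are
exercised deliberately: empty variant tables, empty search databases,
single-member species, saturated distances (an error in NJ rather than a
silent cap), majority ties in the capture scan, and exact vote ties in the
quartet step.
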