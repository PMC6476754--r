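---
title: "Methods: community-scale chloroplast haplotype analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community-scale chloroplast haplotype analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

In species-rich tree communities, most species coexist with congeners. A
maternally inherited, non-recombining marker such as a noncoding
chloroplast spacer (e.g. trnH-psbA) can then be shared across species
boundaries for two very different reasons: retention of ancestral variants
through incomplete lineage sorting (ILS), or introgression following
hybridisation. The two mechanisms leave different community-scale
fingerprints:

* under **introgression**, a species' chloroplast diversity should be
  higher when congeners are locally present (they are the only possible
  donors), and shared haplotypes should concentrate in polymorphic species
  (a successful transfer both adds a haplotype and creates a shared one);
* under **ILS alone**, neither association is expected: retention does not
  care whether congeners grow nearby, and sharing is not tied to
  within-species diversity.

`chplex` implements the full analysis chain that turns a community survey
(a few sequenced individuals from each of hundreds of species, plus a site
inventory and seed-dispersal traits) into those two contrasts, and a
synthetic-community generator that produces datasets with known truth
under controllable ILS and introgression regimes.

# Haplotype collapsing

## The difference metric

Sequences are compared only within genera, on pre-aligned residues; the
pipeline never aligns and never compares residues across genera. Three
classes of difference each contribute **one unit** to the distance between
two aligned sequences (`pairwise_difference()`):

* **substitutions** — columns where both sequences carry a base and the
  bases differ (excluding columns inside a detected inversion);
* **indel events** — one unit per maximal contiguous run of gap-vs-base
  columns. Event counting (rather than per-site counting) is the standard
  treatment of microstructural cpDNA variation: a single replication
  slippage event in a mononucleotide repeat may span many columns but is
  one mutation. `indel_mode = "site"` switches to per-column counting for
  sensitivity analyses;
* **inversions** — one unit per detected reverse-complement segment; small
  inversions in noncoding spacers are single mutational events, so their
  internal columns are removed from the substitution count.

Columns where both sequences have gaps are ignored. Any column where
either sequence carries a symbol outside `{A, C, G, T, -}` (N or another
IUPAC ambiguity letter) is excluded from difference counting altogether
and does not interrupt an indel run. This is a deliberately conservative
choice: ambiguity usually reflects base-calling uncertainty, and counting
such columns as differences would inflate polymorphism — the quantity the
whole analysis is about. The alphabet is validated on input, so anything
else raises an error with the offending position.

## Inversion detection

`detect_inversions()` reports maximal, non-overlapping, gap-free column
intervals of length at least `min_inversion_len` where one sequence's
segment equals the reverse complement of the other's, requiring at least
one mismatching column inside the segment. The mismatch requirement is a
palindrome guard: a segment that is its own reverse complement and
identical in both sequences would otherwise be flagged spuriously.
Intervals are chosen greedily left to right with a longest-first tie
break, which makes output deterministic.

The default `min_inversion_len = 3` reflects two observations: a length-1
"inversion" is indistinguishable from a substitution (A<->T or C<->G), and
length-2 windows flag far too many coincidental complementarities in
random sequence. The parameter is exposed (`--min-inversion-len` on the
command line) because inversion hotspots differ between markers.

## The two-difference rule and single linkage

Two sequences are treated as the same haplotype when they differ by at
most one unit. This absorbs most single-pass sequencing errors into their
parent haplotype at the cost of merging genuinely distinct one-step
haplotypes — a conservative trade-off that understates, never overstates,
polymorphism. Because "at most one unit" is not transitive, a clustering
convention is required: `collapse_haplotypes()` takes the connected
components of the at-most-one-unit graph (single linkage), the most
conservative merger (fewest haplotypes). The brute-force
transitive-closure oracle in the test suite verifies this equivalence on
hundreds of random genera.

One exception restores distinctions that are fixed *between* species:
within a provisional cluster, if all records of one species share a
variant state at exactly one difference unit that no other record in the
cluster carries, that species' records become their own haplotype. A
species-fixed difference is much more likely to be a real diagnostic
variant than a recurrent sequencing error in every individual of one
species. The exception is evaluated per species against the other members
of the provisional cluster, and all qualifying species are split in the
same pass, which keeps the result independent of species ordering.

Haplotype identifiers are genus-scoped (`H1`, `H2`, ... restart in every
genus), assigned by descending member count and then by smallest member
sample id, and the representative sequence is the one carried by the
lexicographically smallest member — all purely for reproducibility of
outputs.

# Community statistics

* **Analyzed species**: species with at least two sequenced individuals.
  Species sequenced once are flagged `excluded` — one sequence cannot show
  polymorphism — but are kept in the species table, and their haplotypes
  still count when deciding whether a haplotype is shared (their existence
  is evidence about other species' sharing status even though their own
  polymorphism is unassessable).
* **Polymorphic**: an analyzed species with at least two haplotypes.
* **Group 1 / group 2**: the species' genus has one / more than one
  species recorded *at the site*, read from the inventory, not from the
  sequenced subset — the question is whether potential donors grow nearby,
  not whether we happened to sequence them.
* **Dispersal classes**: autochorous, anemochorous and hydrochorous
  syndromes are pooled as abiotic; zoochorous and mixed as biotic, so the
  abiotic class is purely abiotic.
* **Sharing universe**: genera with at least two *analyzed* species. This
  deliberately differs from the group-2 definition (which uses the site
  inventory); both filters exist in the code and are never conflated.
* **Incidence unit**: the sharing contrast counts (species, haplotype)
  incidences, not distinct haplotypes — a haplotype found in three species
  contributes three shared incidences. Only the incidence reading makes
  shared and private counts add up to the total number of species-level
  haplotype occurrences in the universe; a per-haplotype reading would be
  inconsistent with per-species polymorphism rows in the same table.
* **Pair sharing**: within a universe genus, an analyzed species pair
  counts as sharing if some haplotype contains both members; the test
  suite asserts the witness-haplotype property directly.

The review report lists every sample whose haplotype is shared across
congeneric species, in deterministic order. Misidentified vouchers mimic
introgression exactly (a "shared" haplotype appears, and the recipient
looks polymorphic), so these samples are where identification effort
should be spent; the report is advisory and feeds no statistic.

# Exact tests

* `fisher_two_sided()` uses the point-probability rule: the p-value is the
  sum of hypergeometric probabilities of all fixed-margin tables whose
  point probability does not exceed the observed one, with ties detected
  at relative tolerance 1e-7 (floating-point masses that should be equal
  rationals differ in the last bits). This is the standard exact
  convention; the suite cross-checks it against full enumeration and
  against `stats::fisher.test()`. All-zero tables return p = 1.
* `binomial_tails()` returns both inclusive tails, P(X <= k) and
  P(X >= k), via stable partial pmf sums, so
  `p_minus + p_plus = 1 + P(X = k)` holds to 1e-12 up to n = 10^4.
* The per-genus scans use a uniform-rate null whose rate is the overall
  fraction **including the focal genus** (the natural reading of
  "compared with the general trend"; excluding the focal genus would use a
  different null per row). The genus-size threshold defaults to 8 analyzed
  species. For pair sharing, the null rate is the sharing fraction over
  all pairs in the whole universe, not only the scanned genera.
* A caveat found while validating against published tables of this kind:
  upper-tail columns and pair-sharing lower-tail columns reproduce
  exactly, but some published per-genus lower-tail polymorphism values are
  not consistent with P(X <= k) at the stated overall rate. The package
  implements the stated definition rather than reverse-engineering such
  cells.

No multiple-testing correction is applied: the scans are descriptive
flags, mirroring how such tables are presented.

# The synthetic community generator

`simulate_community()` emulates the data structure of a plot-scale survey:

* **Species per genus** follow a truncated power law on 1..34 whose
  exponent is solved (at configuration time, by `uniroot`) so the mean is
  2.9 — the skewed few-large-many-small genus-size distribution typical of
  tropical tree plots.
* **Individuals per species** follow a Poisson truncated to 1..11 with
  rate solved for mean 3.6.
* **13%** of species are abiotically dispersed; abiotic recipients get
  their introgression rate multiplied by `abiotic_multiplier` (default 2),
  emulating the higher susceptibility to chloroplast capture of species
  with little seed-mediated gene flow.
* **About a third of site species are never sequenced**
  (`p_unsequenced = 0.33`, matching the ratio of analyzed to recorded
  species in such surveys), so group classification genuinely relies on
  the inventory.
* Each species' **base haplotype** diverges from a random genus ancestor
  by at least two mutation events (mean `divergence = 5`, 15% of events
  short deletions); **private mutation** adds Poisson(`theta = 0.2`) extra
  haplotypes per species. With geometric sampling weights (ratio 0.5) and
  ~3.6 individuals per species this yields a baseline observed
  polymorphism rate near 12%, the level seen in species without congeners.
* **All intended haplotypes of a genus are kept at least two units
  apart** by rejection sampling. This makes the truth well defined under
  the collapsing rule and gives the exact-recovery property: with noise
  off, the number of clusters per species equals the number of distinct
  true haplotypes among its sampled individuals.
* **Noise duplicates** (off by default) perturb an individual's sequence
  by one substitution, only when another individual of the species retains
  the parent haplotype (so the variant is never species-fixed and cannot
  trigger the diagnostic exception) and only at positions that keep the
  copy at least two units from every other haplotype (so noise can never
  bridge two real haplotypes).

## ILS and introgression

Introgression is modelled directly: per ordered congeneric pair, a
Poisson(`intro_rate`) number of events each copy one donor haplotype into
the recipient's pool. Every event is logged with donor and recipient, and
the invariant that species in singleton genera can never participate is
asserted from the truth log.

ILS is modelled as retention of the ancestral haplotype rather than by
coalescent simulation — the analysis consumes only haplotype identity, so
a genealogy would add machinery without changing what the statistics see.
One design decision deserves explanation. The natural-sounding
parameterisation "assign a shared ancestral haplotype to a species pair
with probability `ils_retention`" can only target pairs, i.e. group-2
species, and *adding* a haplotype to both pair members would mechanically
raise group-2 polymorphism — building the introgression signature into
the ILS scenario and destroying the contrast the generator exists to
exercise. Instead, each species independently *retains the undiverged
ancestral base* with probability `sqrt(ils_retention)`: a congeneric pair
then shares the ancestral haplotype with probability `ils_retention`
(matching the parameter's meaning), retention adds nothing to
within-species diversity, and group 1 and group 2 species are affected
identically. This is exactly the null the biology describes: sharing
without extra diversity and without any congener-presence effect.

Scenario defaults (`ils_retention = 0.1`, `intro_rate = 0.1`) were chosen
once so that the introgression scenario moves the congener-present
polymorphism rate from the ~12% baseline to roughly the 30% range a real
community shows, and are dials, not fitted quantities.

## Scenario suite

`scenario_suite()` runs simulation, collapsing, species summaries and
exact tests under four regimes (null, ILS-only, introgression-only, both)
on paired replicate seeds and tabulates per replicate: group-2 minus
group-1 polymorphism rate with its Fisher p-value, and the shared-fraction
difference between polymorphic and monomorphic species' incidences. The
acceptance suite checks: nominal-level type-I behaviour under the null
(the exact test is conservative on discrete tables, so rejection may fall
below but not above the nominal 5%), a positive group contrast and
positive sharing association under introgression-only, and no systematic
group contrast under ILS-only.

# Numerical and reproducibility choices

* Each simulation runs on one RNG stream seeded once; draws are ordered by
  genus, species and event index, so outputs are bit-reproducible and
  `write_community()` files are byte-identical across reruns.
* Fisher tie tolerance 1e-7 (relative); binomial identity tolerance 1e-12;
  p-values are only rounded in presentation columns of the report files
  (3 decimals by default), never internally.
* Pipeline outputs contain no timestamps; the manifest records input
  checksums, parameters and the package version, so identical inputs give
  identical output trees.
* Degenerate inputs: empty strata and all-zero tables raise informative
  classed errors or return the conventional p = 1; scans on degenerate
  null rates (0 or 1) return empty tables rather than undefined tails.

# Problem sizes used in the tests

The validation suite uses sizes chosen to exercise every code path at
desk scale: oracle comparisons on 500 random genera of up to 12 sequences
and 60 columns; Fisher enumeration on 1,000 random tables with totals up
to 60; generator-calibration Monte Carlo on 50,000-200,000 draws of the
component laws (large enough that sampling error is a small fraction of
the 2% calibration band); and scenario suites of 200 replicates per
regime on 80-genus communities with 200-column sequences. Full-scale
communities (238 genera, 450-column spacers) run with the same code and
default configuration.

# Limitations

* The generator is a structural emulator, not a population-genetic
  simulator: no coalescent genealogies, no selection, no spatial
  structure, no abundance differences between species. Passing tests
  establish that the pipeline measures what the generator encodes — not
  that real communities behave like the generator.
* Event-based indel weighting and the ambiguity-exclusion rule are
  documented choices where reasonable alternatives exist; both are
  configurable or isolated enough to swap.
* Alignment quality is an input assumption: the package validates
  equal lengths and alphabets but cannot detect a misalignment.
* The species-diagnostic exception acts only on single-unit diagnostics
  within a provisional cluster, the narrow case its rationale covers.
* Identification error is handled by reporting (the review table), not by
  modelling.
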