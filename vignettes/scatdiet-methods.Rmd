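---
title: "Methods: from scat amplicon reads to predator diet tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from scat amplicon reads to predator diet tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatdiet)
```

# The problem

Carnivore scats contain DNA of the depositing host together with DNA of
consumed prey. Amplifying a short, vertebrate-specific 12S fragment (~97 bp)
from scat extracts and sequencing it gives a mixed read set per sample from
which three things must be recovered: (i) which predator actually deposited
the scat (field identification of fox versus pine marten scats is
unreliable), (ii) which prey taxa each scat contains, and (iii) how diet
composition summarises per predator. `scatdiet` implements that workflow as
a set of pipeable, tibble-in/tibble-out functions, plus a seeded simulator
so that every stage can be validated against a known ground truth.

# Sequence preprocessing

**Dereplication.** Reads are collapsed at 100% identity *and* length,
pooled across samples while per-sample membership counts are retained.
Pooling mirrors the fact that the subsequent alignment and assignment steps
operate on one non-redundant query set; per-sample counts are what the
later per-sample thresholds need. Output is ordered by decreasing cluster
size with lexicographic tie-break on the sequence — every stage in the
package breaks ties this way, so identical inputs give identical outputs.

**Minimum cluster size.** Clusters represented by fewer than three reads
(configurable) are omitted before denoising.

**Denoising.** A greedy UNOISE-style centroid pass in decreasing-size
order: a cluster of size $s$ at Levenshtein distance $d \ge 1$ from an
accepted centroid of size $S$ merges into it when

$$ s / S \le \beta(d) = \frac{1}{2^{\alpha d + 1}}, \qquad \alpha = 2 . $$

Levenshtein (not Hamming) distance is used so that the rule also tolerates
length slippage; `max_distance` can cap the merge radius. No minimum-size
rejection happens inside this step — all cluster sizes are retained, and
total read counts are conserved (merged sizes add to the centroid). The
skew ratio is evaluated against the centroid's *accumulated* size; with the
32-fold steps of $\beta$ between consecutive distances this choice is
essentially never decisive, but it is fixed and documented for
reproducibility.

**Bimera screening.** A cluster $Q$ is removed as a chimera iff two
distinct previously-accepted clusters $P_1 \ne P_2$ exist, each at least 16
times more abundant than $Q$, with a crossover $1 \le k < |Q|$ such that
$Q = P_1[1..k] \,\Vert\, P_2[k{+}1..]$ exactly. Clusters are examined in
decreasing abundance, and only surviving clusters act as parents. This is
deliberately an exact two-parent (bimera) model with an abundance-skew
requirement; partial-match scoring and reference-based detection are out of
scope, and the stage is a plain function so an external tool's output can
be substituted for it.

# Taxonomic assignment

**Hit filtering.** Alignment hits arrive in BLAST tabular form (12
standard columns plus appended percent query coverage, subject ids being
taxon ids of a seven-rank lineage table). Per query, hits are kept when the
bit-score is within the top 2% of that query's best bit-score
(`bitscore >= 0.98 * max`), query coverage is at least 90% and identity at
least 98% — all three thresholds inclusive. The window is read as a
fraction of the maximum bit-score, not a count quantile: with the handful
of hits a 97-bp marker produces, a count quantile would be ill-defined.

**Majority lowest common ancestor (MLCA).** The retained hits are reduced
to their set of *unique* lineages (duplicate reference entries must not
over-weight a taxon) and the seven ranks are walked top-down. At each rank
the modal taxon among lineages consistent with the accepted prefix is
accepted when its share of **all** unique lineages reaches the agreement
threshold (default 0.80); a failed vote or a modal tie stops the walk. The
assignment is the deepest accepted prefix; a single unique lineage is
assigned in full. Assignments that resolve only above order rank are
reported as unassigned. For any agreement above 0.5 this walk provably
returns the deepest rank-prefix whose global share reaches the threshold,
which is exactly the brute-force enumeration the test suite uses as an
independent oracle.

Read counts then propagate from cluster sizes: queries assigned to the same
identity are summed per sample, and unassigned queries accumulate in an
explicit `"unassigned"` bucket so that read totals stay conserved and
auditable.

# Diet filters and summaries

The canonical order is: remove positive-control and unassigned reads (and
samples left empty) → per-sample noise threshold (0.1% of the sample total,
strictly-below removes, at-threshold retains) → roll ambiguous species up
to a configured higher taxon (e.g. ducks to Anatidae) → host confirmation →
host and human subtraction → per-sample per-taxon minimum of 100 reads →
summaries. The source material fixes the individual thresholds but not the
complete ordering; this order is fixed, configurable, and chosen so that a
92-read detection of a prey species in one sample is removed by the
100-read rule, not earlier by the noise filter.

**Host confirmation.** The DNA host is the candidate species with the most
reads in the sample, required to reach a host-read floor (default 100
reads). Hosts are *generally* the most abundant taxon but the floor, not
overall dominance, is the criterion — a heavily parasitised or degraded
sample can have abundant prey reads without invalidating a clear host
signal; `identify_host()` reports dominance alongside. Samples without a
determinate host are dropped, and the *other* predator's DNA is retained
as a diet/contact item rather than treated as a host signal.

**Summaries.** %FOO is the percentage of a group's samples containing a
taxon, with group aggregates (small mammals = Rodentia + Eulipotyphla,
birds, passerines) counting a sample once if any member occurs; samples
whose prey profile became empty still count in the denominator. RRA is by
default the pooled-read proportion per group (per-sample averaging is
available behind `per_sample_mean = TRUE`), summing to 1 per group.
Richness counts distinct prey taxa; the woodland:open ratio classifies a
group's distinct prey taxa by habitat (aquatic/none excluded) and
normalises to percentages. Field-vs-DNA confusion cross-tabulates labels
with per-species misidentification percentages.

# The simulator

`generate_scat_dataset()` realises, per sample: a true host drawn from the
host mix; a field label flipped with probability `misid_rate`; a log-normal
sequencing depth; a host read fraction drawn uniformly from 0.55–0.9 of the
sample (so the host exceeds any single prey taxon); prey included
independently per-taxon with configured probabilities and given Dirichlet
read shares (concentration = `weight * prey_concentration`); human
contamination and positive-control spikes as expected read fractions;
i.i.d. per-base substitutions; and additional single-crossover bimeric
reads at a per-read rate. Everything is recorded in a truth table, and all
randomness derives deterministically from one seed via per-sample
substreams, so identical configurations reproduce outputs byte-for-byte.

Default conditions model the motivating study: 48 scats from a 50:50
fox/pine-marten mix, 29% field misidentification, prey inclusion
probabilities patterned on the per-predator occurrence frequencies of an
afforested-peatland diet (voles and wood mice dominant in marten scats;
deer carrion, frogs and pine marten DNA prominent in fox scats). Sequencing
depth is *not* reported in the source material: the default
`meanlog = log(10000), sdlog = 0.6` is this package's own choice of a
realistic post-filter Illumina depth and is fully configurable, as are the
1e-3/base substitution rate, 5e-3/read bimera rate and 1% human
contamination.

What the simulator does **not** emulate: quality scores and
position-dependent error profiles, PCR duplicates and amplification bias,
index hopping, reference-database incompleteness, and degraded/partial
amplicons. Passing recovery tests therefore demonstrate the correctness of
the pipeline's logic under its stated error model, not robustness to every
artefact of real sequencing runs.

`simulate_hit_tables()` is a shortcut for testing the assignment stages in
isolation: each true (sample, taxon) pair becomes a query with a top
self-hit and decoy hits to related taxa outside the top-2% window; listing
taxa as `ambiguous_taxa` instead places their congeners inside the window
at assignable identity, forcing a legitimate genus-level consensus.

# Numerical and statistical choices

* All thresholds are inclusive ("at least"); removal is strictly-below.
* Ties everywhere break by decreasing size, then lexicographically.
* Percent identity from the built-in scorer is
  $100 (1 - d/L)$ with $d$ the Levenshtein distance and $L$ the longer
  length; coverage is $100 \min(L_q, L_s)/L_q$; the surrogate bit-score
  $2(L - d)$ is monotone in alignment quality, which is all the top-2%
  window requires. Real BLAST tabular output is the primary input path.
* The agreement comparison uses a $10^{-9}$ tolerance so that shares such
  as 4/5 compared against 0.8 are not lost to floating-point rounding.
* Zero-total samples pass through the noise filter untouched and are
  dropped by the control/unassigned removal stage with a logged reason.

The recovery tests are sized to hold on one CPU in a few minutes: the
fuzzed MLCA check runs 1000 random hit sets of up to 8 unique lineages; the
parameter-recovery run simulates 200 scats at the default depth (~2.3M
reads); the exact-identity run 48 noise-free scats. Because roughly 25
taxon-level quantities are checked simultaneously, per-taxon binomial
intervals are Bonferroni-sized (level $0.05/m$) so the *family-wise*
coverage is 95% — testing 25 quantities each at a marginal 95% level would
be expected to fail once or twice by chance alone. Pooled RRA is checked
against a Monte-Carlo band (mean ± $z_{0.05/m}$·sd over 120 truth-level
replicates of the generative model, with a 0.01 absolute floor absorbing
the Monte-Carlo error of the band itself).

# Known limitations

* The MLCA vote is over unique lineages; tools that vote over raw hits
  will differ when reference databases contain many entries per species.
* The bimera model requires exact parent matches; real chimeras with
  additional point errors are caught only after denoising merges those
  errors away, i.e. detection operates at centroid level.
* Host confirmation assumes candidate hosts are known a priori; a scat from
  an unexpected host is reported indeterminate rather than discovered.
* RRA inherits all the usual caveats of read proportions as diet measures
  (tissue digestibility, amplification bias); the package computes it, it
  does not claim it equals biomass.
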