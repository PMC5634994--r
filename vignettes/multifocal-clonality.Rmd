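---
title: "Clonal origin and heterogeneity analysis of multifocal tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal origin and heterogeneity analysis of multifocal tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfclone)
```

# The problem

A patient presenting with several synchronous tumor nodules poses a binary
question with large clinical consequences: are the nodules **independent
primary tumors** (each potentially curable by resection) or a **primary with
metastases** (systemic disease)? Multi-region exome sequencing answers it at
the level of somatic mutations: two tumors descending from one transformed
clone share its truncal mutations, while independently arising tumors draw
their mutations from an enormous space of possible exonic positions and
essentially never coincide. `mfclone` formalizes this decision and the
heterogeneity analyses that build on it — phylogenies, trunk/branch
partitioning, mutation spectra and signature exposures, cancer cell
fractions, driver screening and neoantigen filtering — and pairs them with a
simulator that generates patients with known ground truth.

# Models and procedures

## Tumor-pair relatedness

Let tumor A carry $|A|$ detected non-silent variants and tumor B $|B|$, with
$s$ shared, in a universe of $N$ callable exome positions (default
$3\times 10^7$, configurable). Under independent accumulation the shared
count is hypergeometric, and we report the upper tail
$P(X \ge s)$. The verdict is *independent* iff the tail probability is at
least $\alpha$ (default 0.01) **and** the shared fraction
$s/\min(|A|,|B|)$ is below 0.05. The fraction guard exists because a single
coincidental hotspot mutation can be extremely "significant" under the
hypergeometric null at $N = 3\times10^7$ while being biologically
unremarkable; conversely a metastatic pair shares on the order of its whole
truncal set, far above 5%. The underlying studies report the absence of
significantly overlapping variant sets descriptively without naming a
statistic, so both the test and its thresholds are this package's design
choices, exposed as `alpha`, `max_shared_frac` and `exome_positions`.

The shared-fraction denominator is $\min(|A|,|B|)$: the smaller tumor bounds
how much overlap is achievable, so the guard remains meaningful when variant
burdens are unbalanced.

## Presence thresholds

A variant is present in a region when it has at least `min_alt_reads` (3)
alternate reads and a VAF of at least `min_vaf` (0.02). At the ~200–250x
depths typical of exome studies of this design these defaults suppress
sequencing noise while keeping subclones at CCF ~0.1 detectable; published
presence/absence heat maps do not state their thresholds, so both are
configuration keys rather than constants.

## Maximum-parsimony phylogenies

Trees are built on the binary presence/absence matrix of one tumor's
regions, rooted by an all-absent normal outgroup. For up to 8 region leaves
every rooted topology — $(2n-3)!!$ of them via leaf insertion — is scored
with the Fitch algorithm vectorized across variants, which is exact at this
scale (multi-region designs rarely exceed 4–5 regions per tumor). Beyond
8 leaves a neighbor-joining tree on Hamming distance supplies the topology
and Fitch supplies scoring and placement. Equally parsimonious topologies
are resolved by a lexicographic canonical encoding of the tree shape, making
results order-independent and deterministic. Parsimony over likelihood is
deliberate: the characters are binary presence calls, branch counts are the
quantity of interest, and exactness is checkable against an independent
implementation.

After scoring, each variant is placed on the edge where its state changes
from absent to present (Fitch final states, preorder). A variant forced to
change more than once (homoplasy — e.g. a recurrent hotspot present in both
tumors of an independent patient) is placed at its first gain in preorder
and flagged rather than rejected.

**Trunk and branch.** A mutation is *truncal* when present in every sampled
region of the tumor — the standard multi-region-sequencing convention — and
*branched* otherwise; the ITB index is the ratio of branched to truncal
counts. With zero truncal mutations the ratio is reported as `Inf` with a
warning rather than an error, since downstream summaries can handle it.

## Cancer cell fractions

The expected VAF of a mutation present in a fraction CCF of tumor cells,
on one copy per carrying cell, is

$$f(\mathrm{CCF}) = \frac{p \cdot \mathrm{CCF}}
  {\mathrm{CPN}_{mut} \cdot p + \mathrm{CPN}_{norm}(1-p)}$$

with purity $p$ and local tumor/normal total copy numbers. The denominator
is the average number of allele copies per sampled cell, the numerator the
mutated copies. Because $f$ is linear in CCF the estimator is a closed-form
inversion of the observed VAF, clipped to $[0,1]$ (the pre-clip value is
kept in `ccf_raw`). Uncertainty comes from an exact Clopper–Pearson binomial
interval on the VAF pushed through the same inversion — exact intervals were
chosen over Wald because depths vary and alternate counts can be small. A
mutation is *clonal* when the CI upper bound reaches `clonal_cut` (0.95):
the data cannot exclude presence in essentially all tumor cells.
Records below `min_depth` (10) are *indeterminate*. The CI method and the
clonal threshold are not dictated by any published rule beyond "defined
according to the confidence interval", so both are configuration keys.

**Multiplicity.** The model fixes mutation multiplicity at 1, matching the
form of the equation above. Mutations on amplified alleles therefore have
their CCF underestimated; full multiplicity estimation belongs to
purity/ploidy callers and is out of scope. This is the package's main known
limitation for heavily amplified loci.

**Oligoclonality.** Per region, alternate read counts are modelled as a
$K$-component binomial mixture whose success probabilities are CCF centers
mapped through $f$, fitted by EM with seeded restarts; $K \in 1..5$ is
selected by BIC with $2K-1$ free parameters, and the region is oligoclonal
at $K \ge 2$. This is an intentionally lightweight stand-in for Bayesian
clonality machinery (Dirichlet-process or variational mixture models are
explicitly not re-implemented): it detects well-separated CCF clusters,
which is what the downstream oligoclonality statement needs, and it is
deterministic under a seed. Fewer than 10 adequate-depth variants yields an
explicit "insufficient data" result instead of a fragile fit.

## Mutation spectra and signature refitting

SNVs are binned into the canonical 96 channels: 6 substitution classes on
the pyrimidine strand ($C{>}A, C{>}G, C{>}T, T{>}A, T{>}C, T{>}G$) times 16
flanking-base contexts, ordered class-major then 5' then 3', names like
`A[C>T]G`. Purine-reference SNVs are reverse-complemented before binning, so
a call set and its full mirror produce identical spectra (a tested
invariant). Contexts come from the call's `context3` field or a reference
FASTA; a context whose middle base contradicts the reference allele is an
error, not a warning, because it indicates corrupted input.

Exposures are refit by non-negative least squares of the normalized spectrum
on catalog rows, followed by iterative pruning: signatures whose normalized
weight falls below `min_weight` (0.06, the widely used refitting default)
are dropped and the remainder refitted until stable. Weights are reported
normalized to sum 1, with the cosine similarity of the reconstruction as the
fit quality. One clarification of intent: pruning restricts the active set,
so the least-squares residual after a drop can only grow — the monotonicity
that holds is within refits of a fixed active set, and the tests check
recovery accuracy and reconstruction quality rather than a cross-iteration
residual ordering.

Samples cluster by average-linkage hierarchical clustering on cosine
distance of normalized spectra, cut at $k = 2$ by default (the typical
first-order split of a cohort by dominant mutational process); $k$, metric
and linkage are arguments. Trunk-versus-branch exposure differences carry
percentile bootstrap intervals from resampling mutations within each
spectrum (1000 seeded replicates by default).

The package bundles no third-party signature catalog. A synthetic,
well-separated catalog (`synthetic_signature_catalog()`) supports simulation
and tests; a real catalog loads from a documented TSV (rows = signatures,
96 ordered channel columns). Spectrum normalization against genome/exome
context frequencies is the user's responsibility via the catalog they
supply.

## Driver screening

The rule engine follows a two-branch design against user-supplied tables
(a gene census with recessive and candidate-list flags, and a
COSMIC-like known-somatic-variant table; the real COSMIC export is
license-restricted and never bundled — small synthetic fixtures ship for
tests). The candidate-list gate applies before either branch, and can be
disabled. Branch 1: exact mutation (genomic key, or same protein change in
the same gene — aggregated databases key by amino-acid change), same site
(same genomic position, or same residue), or at least three known mutations
within 15 bp (inclusive, genomic coordinates). Branch 2: recessive census
gene, stop-gain/frameshift/splicing effect, and SIFT < 0.05 or
PolyPhen > 0.995; absent scores fail the clause conservatively. "Same site"
is matched at both the genomic and protein level because the underlying
definition is ambiguous between them; the fired rule records which.
Verdicts are deterministic and monotone: adding known-variant evidence can
never un-flag a driver.

**Pathway convergence.** Each tumor contributes one most prominent driver
(rule priority exact > same-site > window > recessive-deleterious, ties by
lowest SIFT then gene name — a formalization of what is otherwise expert
judgment). The statistic is the number of tumors hitting the modal pathway;
its null distribution comes from uniform random pathway reassignment
(10 000 seeded permutations), cross-checked in tests against exact
enumeration for small designs.

## Neoantigen filtering

For a missense substitution at protein position $m$, every window of length
$L \in \{9,10,11\}$ containing $m$ and fully inside the protein yields a
mutant/wild-type peptide pair — 30 pairs for an interior residue. Candidates
require mutant affinity strictly below 500 nM **and** strictly below the
wild-type affinity; exactly 500 nM and WT ties are rejected. Affinities are
external inputs (a TSV of peptide/allele/nM); a deterministic hash-based
mock provider supports tests and simulated loads but carries no biology.
The wild-type comparison is per (peptide, allele) pair, not best-over-
alleles. Only missense SNVs are enumerated; frameshift neo-ORFs are counted
separately and not enumerated.

# The simulator

`simulate_patient()` generates what the analyses assume real data look
like:

- **Scenarios.** `independent_primaries` draws every tumor's loci without
  replacement from one pool, so tumors share zero variants by construction;
  `metastatic` emits a single truncal clone spanning all regions of all
  tumors (true CCF 1 everywhere), then tumor-private branches.
- **Clonal structure.** Each tumor gets a uniformly random rooted topology
  over its regions; each branch clone carries its own mutations (present in
  exactly its clade), plus single-region subclones at configured CCFs.
- **Mutational processes.** Trinucleotide channels are drawn from the
  tumor's signature mixture over the catalog; half of the emitted records
  are represented on the purine strand to exercise strand collapse.
- **Reads.** Per variant and region, total depth is Poisson around the mean
  coverage and alternate reads are binomial at $f(\mathrm{CCF})$ under the
  region's purity and the locus's simulated whole-arm copy number — exactly
  the forward model the CCF estimator inverts.
- **Drivers.** A menu of recurrent lung-cancer lesions (synthetic but
  stable coordinates matching the bundled known-variant fixture) is planted
  truncally, one per tumor by default.

Defaults are chosen to emulate a small multifocal lung-cancer exome study:
2 tumors x 2 regions, ~150 truncal plus 40-per-branch plus 2x30 subclonal
mutations per tumor (a few hundred somatic alterations per tumor), mean
coverage 244x, purity 0.6, subclone CCFs 0.6 and 0.3, 20% synonymous
passengers, whole-arm copy numbers in {1,2,3,4} at proportions
(0.05, 0.85, 0.05, 0.05). Seeding fans a master seed out to per-tumor child
seeds, so adding a tumor never perturbs earlier tumors and identical
configurations are byte-identical.

What the simulator does **not** emulate: sequencing error and strand
artifacts, germline contamination, mapping bias, focal copy-number events
and LOH, mutation multiplicity > 1, clustered mutational processes along
the genome, and indels (structural realism stops at SNVs with read counts).
Passing recovery tests therefore demonstrate correctness of the estimators
under their own forward model and robustness to binomial/Poisson sampling
noise — not robustness to caller artifacts in real data.

# Numerical and degenerate-input choices

- CCF inversion is algebraically exact; round-trips recover the generating
  CCF to machine precision across a purity/copy-number grid.
- Clopper–Pearson bounds use `qbeta` tail quantiles with the conventional
  closed forms at 0 and $n$ successes.
- The EM for oligoclonality clamps success probabilities away from 0/1,
  uses 3 seeded restarts per $K$, and reports occupied components only.
- A degenerate CCF geometry ($f(1) = 0$, e.g. homozygous-deleted locus
  claimed at purity 1) yields an *indeterminate* record, not an error.
- Zero spectra are excluded from clustering with a warning; a zero-mutation
  spectrum is a fit error since exposures are undefined.
- Unknown effect strings downgrade to `other` with a warning; unknown
  config keys and overlapping copy-number segments are hard errors.

# Problem sizes in the tests and acceptance script

The test suite and `scripts/acceptance.R` exercise the pipeline at sizes
chosen to make the statistical checks sharp while staying desk-scale: 50
simulated patients per scenario for origin discrimination, 100 random
5-region/40-variant matrices against an independent exhaustive-parsimony
oracle (phangorn), 20 replicates each for signature-mixture recovery
(n = 2000–5000 mutations) and for 60/40 CCF-mixture detection, 900 clonal
variants for classification rates, and 20 000 permutations for the
convergence p-value. All randomness descends from a single seed argument.

# Limitations

Beyond the simulator's scope above: purity is an input, never estimated;
SIFT/PolyPhen and MHC affinities are consumed, never computed; subclonal
deconvolution feeding tree tips is out of scope; the relatedness test
assumes variant calls of the two tumors are comparable (same calling
pipeline and depth regime). The exhaustive parsimony search is exact but
exponential — beyond 8 regions the NJ seed makes results heuristic, and the
canonical tie-break, while deterministic, is arbitrary among equally
parsimonious trees.
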