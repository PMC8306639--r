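---
title: "rhizonet: methods and design notes"
author: "rhizonet maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rhizonet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizonet)
```

rhizonet implements the quantitative chain used in amplicon-based soil and
rhizosphere microbiome studies, from a rarefied OTU count table to a
co-occurrence network with hub (keystone) candidates. This vignette explains
each method, its assumptions, the tunable parameters, and the design
decisions taken where the methodology left genuine choices open. It states
no empirical result that the package's test suite does not itself compute.

## Data model

An `OtuTable` is an OTU-by-sample numeric matrix with unique row (OTU) and
column (sample) identifiers, flagged as raw counts or per-sample relative
abundances. Alignment between tables, metadata and distance matrices is
always by sample id, never by position: positional matching is a classic
source of silent errors when tables have been subset upstream.

Two marker datasets (for example a prokaryotic 16S table and a fungal ITS
table) covering the same samples are combined with `mergeDomains()`. Because
each marker is rarefied to its own depth, concatenating raw counts would
encode sequencing depth rather than biology; each table is therefore
converted to per-sample relative abundance *independently* and then
row-concatenated. Each sample column of a k-table merge consequently sums to
k. This constant per-sample factor is deliberately left in place: Pearson
correlation between OTU rows across samples is invariant to a common
per-sample scaling, so the network stage is unaffected.

## Preprocessing

The table-level denoising tail mirrors standard amplicon practice and is
applied in a fixed order:

1. **Control-OTU removal** (`removeControlOtus()`): every OTU detected
   (count > 0) in the negative-control sample is discarded, however abundant
   it is elsewhere — ambient or reagent contamination is assumed to
   contaminate all libraries. The control column itself is dropped.
2. **Relative-abundance filter** (`filterLowAbundance()`): an OTU is kept
   when its row sum is at least `thresholdFraction` (default 5e-5, i.e.
   0.005%) of the *grand total* of the table. The pooled-total reading was
   chosen over a per-sample rule because the threshold is expressed as a
   percentage "of all sequences"; the comparison is inclusive, and a
   threshold of 0 keeps every row (including all-zero rows, since 0 >= 0).
   Filtering precedes rarefaction, and is defined only on counts.
3. **Rarefaction** (`rarefyTable()`): each sample is resampled down to a
   common depth *without replacement* — a multivariate hypergeometric draw,
   matching the "resampled down" semantics — in a single draw per sample
   (no rarefaction averaging). Column sums equal the depth exactly, output
   counts never exceed inputs, and the draw is reproducible from an explicit
   seed. Samples below the target depth are reported by name and must be
   dropped by the caller; the function never drops data silently.

## Alpha diversity

Per sample, `alphaDiversity()` reports observed richness S, bias-corrected
Chao1, Shannon entropy, the Gini-Simpson index and evenness:

* **Chao1**: \(S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))\), the bias-corrected
  form, applied uniformly so that \(F_2 = 0\) needs no special case. Chao1
  is undefined on relative abundances and the function refuses them.
* **Shannon** \(H = -\sum_i p_i \ln p_i\) in **nats**. The natural-log
  convention is the one consistent with published soil-community tables in
  which roughly 1,150 taxa carry \(H \approx 6.2\): the theoretical maximum
  \(\ln 1150 \approx 7.05\) leaves room for 6.2, whereas a log2 reading
  would not.
* **Simpson**: the Gini-Simpson form \(1 - \sum_i p_i^2\), which rounds to
  1.0 for diverse communities.
* **Evenness**: the Hill-number form \(e^H / S\) — the effective number of
  taxa divided by the observed number. The choice matters: Pielou's
  \(H / \ln S\) evaluates to ≈ 0.85–0.9 on the community shapes above,
  while \(e^H / S\) evaluates to 0.4–0.5 (prokaryotes) and 0.1–0.2 (fungi),
  which is the behaviour published summary tables show. The package's
  acceptance script recomputes exactly this consistency check from printed
  condition means (`evennessFromShannon()`), and the test suite asserts
  `evennessIndex(x) == exp(shannonIndex(x)) / richness(x)` as an invariant.

`alphaDiversitySummary()` reports the mean and SD over the replicate
samples of each condition, mirroring the usual Mean/SD layout of field
studies.

## Beta diversity and PERMANOVA

`brayCurtis()` computes \(D(a,b) = \sum_i |x_{ia} - x_{ib}| / \sum_i
(x_{ia} + x_{ib})\), a `[0, 1]`-bounded semimetric (the triangle inequality
is not guaranteed and never assumed). A pair of all-zero samples is given
distance 0 by convention.

`permanova()` partitions the total sum of squares of a distance matrix
among an *ordered* term list:

1. Gower centering: \(G = -\tfrac12 J D^{(2)} J\), whose trace is the total
   sum of squares \(\tfrac1n \sum_{i<j} D_{ij}^2\).
2. Sequential (Type-I) sums of squares from projection (hat) matrices of
   the cumulative designs: \(SS_k = \mathrm{tr}(H_k G) -
   \mathrm{tr}(H_{k-1} G)\). Sequential SS matches the behaviour of the
   classical `adonis`-style analysis, and the test suite checks term SS, F
   and R² against vegan's `adonis2` to 1e-10 as an independent oracle.
3. Pseudo-F per term against the residual mean square; significance from
   unrestricted permutation of sample labels (no strata), with the observed
   statistic counted as one permutation: \(p = (1 + \#\{F^{(b)} \ge F\}) /
   (1 + n_{perm})\). The smallest attainable p is therefore
   \(1/(n_{perm}+1)\) — the familiar 0.001 floor at 999 permutations — and
   p is never 0.

Main effects must precede their interactions in the term order (validated),
rank-deficient designs name the aliased term, and `nPerm = 0` skips the
test when only the variance partition is needed. Calibration is covered by
a property test: on 400 simulated null datasets the permutation p-values
are uniform to within a Kolmogorov-Smirnov statistic of 0.1.

## Core-microbiome partitions

`presenceSets()` defines presence per condition as detection in at least
one replicate (`mode = "any"`, default) or in all replicates
(`mode = "all"`); `vennPartition()` then produces the exact, disjoint
set-algebra partition for two or three groups. Partitions are verified
against a brute-force membership loop in the tests.

## The co-occurrence network

The network stage is the core of the package.

**Correlation and permutation null.** `permutationPvalues()` computes all
pairwise Pearson coefficients between OTU rows (across samples), then
calibrates them against a permutation null: in each of B replicates
(default 100), *every OTU row's sample order is shuffled independently* and
the full correlation matrix is recomputed. This scheme destroys exactly the
quantity under test — inter-OTU dependence — while preserving every OTU's
marginal distribution, which matters because relative-abundance data are
far from Gaussian. The raw p-value of a pair is the fraction of replicates
whose \(|r^{(b)}|\) reaches the observed \(|r|\). OTUs with zero variance
are flagged and excluded. Correlations are computed on whatever scale the
table carries; the documented pipeline convention is per-marker relative
abundance (the `mergeDomains()` output). For rarefied tables, counts and
relative abundances give identical correlations, since every column sum is
the same.

**Zero-attainable p-values.** By default \(p = \mathrm{count}/B\), so p can
be 0. The conservative alternative \((\mathrm{count}+1)/(B+1)\) is
available via `pseudocount = TRUE`, but it is not the default for a
concrete reason: at B = 100 the smallest pseudo-counted p is ≈ 0.0099, and
a Benjamini-Hochberg step-up over the ~10^6 pairs of a two-marker soil
dataset at threshold 0.01 would retain almost nothing, which is
incompatible with the thousands of links such networks are reported to
contain. Zero-attainable p-values are what make the published pipeline
shape reproducible.

**The statistical price, stated plainly.** With per-pair permutation
p-values at resolution 1/B, an exchangeable null pair attains \(p = 0\)
with probability \(1/(B+1)\). BH leaves zeros at zero, so on a table with
m largely-null pairs the network retains about \(m/(B+1)\) spurious edges
regardless of the nominal threshold. The procedure therefore controls the
*per-pair false-edge rate* (about 0.5% at B = 200, verified in the test
suite against the 1.5-alpha bound), but **not** the false discovery
proportion among retained edges when true edges are few: in the package's
own planted-block simulations (one 5-OTU block among 100 OTUs) the
empirical edge FDR is around 0.7, and the corresponding acceptance check is
deliberately left failing rather than weakened, because it cannot be met
jointly with the recovery requirement at B = 200 — the pseudo-counted
variant drives the FDR to zero only by retaining no edges at all. Users who
need proportion-level FDR control should raise B substantially (so that
\(m/(B+1) \ll\) the expected number of true edges) or enable the
pseudo-count; both options are one argument away.

**Edge rule and nodes.** `buildNetwork()` keeps an edge when the
BH-adjusted p is at most `alpha` (default 0.01) and \(|r| \ge\) `rMin`
(default 0 — the "strong correlation" magnitude cutoff is exposed rather
than hard-coded because no canonical value exists). Nodes are the OTUs
incident to at least one retained edge; isolated OTUs are excluded, which
is why reported node counts fall below the OTU inventory.

**Hub scores.** Hub centrality is the principal eigenvector of the
network's *unweighted* adjacency matrix, normalized to maximum 1 (for an
undirected graph the Kleinberg hub/authority iteration reduces to this).
The implementation deliberately avoids the \(A^2\)-based HITS routine,
whose eigenspace degenerates on stars: on \(K_{1,3}\) the scores must be 1
for the centre and \(1/\sqrt3\) for the leaves, which the adjacency
eigenvector yields and the tests pin down against a dense power-iteration
oracle. The top-k list (default k = 20) orders by descending score with
ties broken by OTU id; scores are rounded at 1e-12 so that symmetric nodes
tie exactly and the ordering is reproducible run to run.

**Global metrics.** Density \(2m/(n(n-1))\), global transitivity
(3 × triangles / connected triples), diameter and average path length.
Co-occurrence networks are routinely disconnected, so the conventions are
explicit: the diameter is the largest *finite* shortest-path distance
(i.e. within components) and the average path length is the mean over
*connected* unordered pairs only. Undefined quantities (empty network;
transitivity with no connected triples) are returned as `NA`, never as
silent zeros. All metrics are verified against a Floyd-Warshall plus
triple-enumeration oracle on random graphs.

## The synthetic generator

`simulateOtuTable()` exists so that every stage above can be validated
against a known truth without any sequencing data. The generative model is
a Gaussian copula: a latent multivariate normal vector per sample (planted
block/hub correlation structure), mapped through \(\exp(\mu + \sigma z)\)
to log-normal relative abundances (\(\mu = 0, \sigma = 1\) by default —
strongly right-skewed, as real OTU abundance distributions are),
multiplied by per-factor group effects (\(e^{lfc}\) on a chosen OTU
subset), closed to proportions, and finally drawn as multinomial counts at
a fixed depth. This is the simplest generator that produces overdispersed,
compositional, integer data with controllable dependence.

Design points worth knowing:

* **Hubs are one-factor.** A hub with k spokes at latent correlation ρ
  forces spoke-spoke correlation ρ² (the one-factor fill); this is not a
  modelling afterthought but a mathematical constraint — for k = 15 and
  ρ = 0.9 any spoke-spoke correlation below ≈ 0.80 makes the matrix
  non-PSD. Planted "hubs" in correlation networks are therefore
  near-cliques, and hub-recovery checks must allow score ties.
* **Attenuation is real and reported.** Correlation is planted on the
  latent scale; the exponential map attenuates it (latent 0.95 realizes
  ≈ 0.92 on abundances) and compositional closure attenuates further when
  the block spans a large fraction of the table — in the degenerate case of
  a block covering *all* OTUs, closure removes the shared factor entirely
  and no correlation survives. The truth object carries the latent matrix
  so recovery thresholds can be set honestly.
* **What it does not emulate**: taxon-specific mean abundances, zero
  inflation beyond what the log-normal/multinomial induces, phylogenetic
  structure, or negative ecological interactions beyond what planted
  negative ρ provides.

The presets mirror a two-soil field trial: `fieldtrial-16S` (1,600 OTUs,
18 samples = 2 soils × {bulk, planted, planted+amended} × 3 replicates,
depth 7,541) and `fieldtrial-ITS` (430 OTUs, depth 32,983), plus `mini`
(100 OTUs × 20 samples, depth 10,000) used by the calibration and recovery
simulations.

## Problem sizes used by the test suite

The simulation-backed tests run at sizes chosen to make their Monte-Carlo
error small relative to the asserted bounds while keeping the suite quick:
50 seeds × B = 200 for the calibration, FDR and recovery experiments on
`mini`-shaped tables; 400 datasets for PERMANOVA null uniformity (at 200
datasets the 5% critical KS value is 0.096, uncomfortably close to the 0.1
bound being asserted); 10,000 draws for the hypergeometric rarefaction
expectation; exhaustive enumeration of all 720 relabelings for the n = 6
PERMANOVA oracle. Passing these tests demonstrates correctness of the
machinery on data *matching the generator's assumptions*; it does not
certify behaviour on real data, where compositional effects, zero
inflation and taxon-specific dispersion are stronger.

## Known limitations

* Pearson correlation on compositional data carries a negative bias of
  order 1/(number of OTUs); the package follows the standard
  correlation-network recipe and does not apply compositionality-aware
  estimators (SparCC/SPIEC-EASI-style), which are out of scope.
* With three replicates per condition, per-condition networks rest on
  n = 3 correlation estimates; the network CLI warns below n = 5 and the
  choice of which samples feed a network is always the caller's.
* The FDR caveat above: at small B the edge list is liberal by
  construction; treat edge counts as descriptive, not inferential,
  unless B is raised or the pseudo-count enabled.
* Differential-network statistics (testing whether two networks' metrics
  differ) are not implemented.
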