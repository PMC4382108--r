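---
title: "Methods: pseudo-testcross linkage mapping and draft-genome anchoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudo-testcross linkage mapping and draft-genome anchoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Rubber tree (*Hevea brasiliensis*) has 18 chromosomes and a ~2.15 Gb,
repeat-rich genome whose draft assembly is fragmented into over a million
scaffolds. anchormap implements the analysis route that turns targeted
genotyping of an outbred F1 family — two heterozygous parents and ~149
offspring — into a linkage map, and uses that map to anchor assembly contigs
and scaffolds, to detect assembly discordance, and to fold in legacy
microsatellite map information. A synthetic-data module generates crosses
with the same statistical structure so the entire pipeline is testable
without any external download.

# The cross and its segregation types

In an outbred ("pseudo-testcross") F1 design each SNP falls into one of four
configurations, determined by the parental genotypes:

| type | parents | offspring ratio | informative meioses |
|------|---------|-----------------|---------------------|
| `lm` | ab x aa | 1:1             | P1 only |
| `np` | aa x ab | 1:1             | P2 only |
| `hk` | ab x ab | 1:2:1           | both (het offspring ambiguous) |
| `fi` | ab x cd | 1:1:1:1         | both, fully resolved |

Markers heterozygous in only one parent behave like a backcross for that
parent's meioses. `hk` markers are informative in both parents but the
double-heterozygote offspring class does not reveal which parent transmitted
which allele; `fi` markers (four distinguishable alleles, including shared-
one-allele cases such as ab x ac) resolve both transmissions.

# Genotype QC cascade

The filter cascade mirrors standard practice for capture-based genotyping of
a mapping family, in this fixed order:

1. **Call replacement.** Any call with total read depth below 20 becomes a
   no-call. Any heterozygous call whose two allele read depths reject a
   symmetric binomial split (exact two-sided test at level `1e-3`) also
   becomes a no-call. The level is configurable; `1e-3` balances removing
   allele-imbalanced artifacts against discarding ordinary binomial
   fluctuation at depth 20-100. The test applies to heterozygotes only —
   the 0.5 allele-balance null does not exist for homozygous calls, which
   are filtered by depth alone.
2. **Call rate.** Markers with fewer than 80% of samples called — parents
   and offspring both count, since "samples" is the natural denominator for
   a 151-sample VCF — are dropped.
3. **Parental consistency.** Markers with a parental no-call are dropped; so
   are markers where neither parent is heterozygous (they carry no
   segregation information), and markers where any offspring genotype is
   impossible under transmission of one allele from each parent. The
   genotype-space rule is deliberately stronger than mere allele presence:
   for A/G x A/A parents an offspring G/G contains only parental alleles
   yet cannot occur.
4. **Segregation.** A chi-square goodness-of-fit test (no continuity
   correction, so the statistic matches the brute-force multinomial form at
   every df) against the type's Mendelian ratio; markers with p below
   `1e-5` are dropped as distorted, as are markers with fewer than 10
   called offspring, for which the test is meaningless.

Each stage reports exact input/output counts, so planted-artifact recovery
is testable call by call.

# Two-point linkage model

For a marker pair, each offspring is reduced to a joint *transmission
state*. The cross-tabulation of joint states is a sufficient statistic: its
per-category probability is, up to a constant that cancels in the LOD, a
polynomial of degree at most two in the recombination fraction $r$, with
coefficients fixed by the two segregation classes and the phase
configuration of each informative parent (coupling or repulsion). For
example, for an `hk` x `hk` pair in coupling the double-het x double-het
category has probability $2[(1-r)^2 + r^2]$ — the classical ambiguous
class.

The likelihood is maximised by EM over the unobserved transmissions,
jointly with an outer maximisation over the at most four phase
configurations; initialisation is at $r = 0.25$ with restarts at 0.05 and
0.45, convergence when the change in $r$ falls below `1e-6` (at most 200
iterations), and ties across phases break toward smaller $r$. The LOD is
$\log_{10} L(\hat r)/L(0.5)$. Pairs informative in strictly different
single parents (`lm` x `np`) share no meioses and are defined to return
$r = 0.5$, LOD 0. All pairs of one class combination are fitted
simultaneously: indicator-matrix products give every cross-tabulation at
once, and the EM update is elementwise across pairs, which is what makes
all ~250k pairwise estimates of a 700-marker panel feasible in seconds.
The estimator is verified in the test suite against an independent
grid-search likelihood oracle (step `1e-4`, all phases).

# Grouping, threshold selection, bins

Linkage groups are connected components of the graph with edges at
LOD $\ge$ threshold (exact single linkage; verified against a union-find
oracle). Maps are built for every threshold in 8-18 and one is selected by:
group count (over a minimum group size of 5 markers, so dust components do
not dominate the count) closest to the expected chromosome number; ties
broken by contig-level co-grouping agreement with the reference
(microsatellite) map, then by the higher threshold. Components below the
size floor are reported as unplaced rather than promoted to groups.

Co-segregating markers are collapsed into *bins* (non-redundant marker
positions). Signatures are compared up to allele relabelling. The
`collapse_bins()` default is strict — no-call patterns must match — but the
map fit uses the wildcard variant (a no-call matches either state) because
at realistic no-call rates (~10%/call) strict identity leaves almost every
SNP alone in its own bin, while published capture maps of this design
collapse thousands of SNPs into a few hundred positions per group despite
missing data. All member SNPs are retained and reported at the bin
position, since the purpose of the map is to place as many contigs as
possible.

# Ordering and positions

Bin-pair recombination fractions (member-pair estimates pooled by
informative-meiosis count) are converted to cM by the Haldane map function
$d = -50\ln(1-2r)$, consistent with the no-interference crossover process
of the simulator. Two-point distance estimates saturate into noise beyond
roughly 40 cM, so the distance matrix is rebuilt from confident pairs only
(LOD $\ge$ 3) and completed by shortest paths; bins that share no
informative meioses (a P1-only bin against a P2-only bin) also get their
distance by this completion. Ordering then proceeds by a greedy
nearest-neighbour chain seeded from the most eccentric bin (with
principal-coordinate and tightest-pair seeds as alternatives), refined by
2-opt reversals and Or-opt segment relocations, and polished by iterated
weighted-least-squares positioning (regression mapping) over all confident
pairs, with delta-method inverse-variance weights on the cM scale. The
polish pools many distance estimates per bin and is what makes the order of
clusters a few cM apart robust to single noisy estimates; it remains a
two-point method — no error-correction HMM is attempted. Positions are
cumulative adjacent distances from 0, rounded at `1e-6` cM so that
co-segregating bins share one exact position; orientation is canonical
(the terminal bin with the smallest marker id first), making results
invariant to input orientation up to reversal.

A practical limit worth stating: markers inside one contig span well under
0.1 cM, so 149 offspring essentially never show a recombinant between them.
Their relative order is undefined by the data — any two-point (indeed any)
method can only tie them. Order-recovery checks in the tests therefore
compare estimated against true order at a 1 cM resolution floor (about
three crossover events at this family size); sub-resolution pairs are tied,
not scored.

# Anchoring and discordance

Contigs are assigned to the group holding the majority of their SNPs (ties
flagged unresolved, as the published analyses resolved such cases by hand),
positioned at the median SNP position, and flagged when SNPs span more than
10 cM within a group or hit multiple groups — the signature of collapsed
repeats. Scaffolds inherit placements from their contigs; flagged are
internal gaps of at least 20 cM and scaffolds whose uniquely assigned
contigs land in different groups. Group labels are matched to the reference
map by maximum-weight bipartite matching on shared-contig counts.
Scaffolds carrying only a reference (microsatellite) anchor are added with
the reference group label and a position interpolated linearly between the
two nearest reference markers that also have SNP placements; with no
flanking co-anchored pair they are placed at group level only.

# Primer placement rules

Legacy microsatellite markers are anchored by their primer blast hits:
a hit passes the basic filter when the alignment covers one of the two
3'-terminal bases and at least 80% of the primer. Pairs with passing hits
on one contig require a unique convergent product of at most 500 bp
(product length measured between outermost subject coordinates, the e-PCR
convention; uniqueness is genome-wide, the stricter reading). Pairs
spanning two contigs require a 100% match over at least 70% of each primer,
entirely within 300 bp of a contig end, and exactly one qualifying hit per
primer.

# The synthetic cross

`sim_config()` fixes the study conditions: 18 chromosomes of 120 cM, 149
offspring, ~50 markers per chromosome grouped into contigs of 1-5 markers
(~2.9 per contig on average, matching the SNPs-per-contig density of
capture maps of this design), contigs grouped into scaffolds
(1 + Poisson(2) contigs each). Meioses follow a no-interference crossover
process, so recombinant fractions are exactly Haldane. Depth is
negative-binomial (mean 60, size 5 — capture data is over-dispersed),
heterozygous allele depths are binomial at 0.5, genotyping errors replace
0.5% of calls with another genotype from the locus's genotype space,
3% of calls are no-calls, 2% of loci are transmission-distorted (each het
parent transmits its favoured allele — the lexicographically first of its
pair, so shared-allele parents are skewed in the same direction, as
locus-level gametic selection would act — with probability 0.8, applied at
the locus only: the simplest mechanism that triggers the segregation
filter), and 1% of multi-marker contigs have a marker subset relocated to a
second true position (half within-chromosome at $\ge$ 30 cM, half to
another chromosome), emulating collapsed repeats. Chromosome length, depth
and rate defaults are choices a capture-genotyping study of a large plant
genome would find realistic; none is derived from data.

What the generator does *not* emulate: read-level sequence (no capture
chemistry, no mapping bias), linked genotyping errors (errors are
independent across calls), crossover interference, and segregation
distortion gradients along chromosomes. Passing recovery tests on this
generator therefore demonstrates correctness of the statistical machinery
under its stated model, not robustness to every artifact of real capture
data.

# Problem sizes used in the checks

The recovery checks run the full pipeline on the default 18 x 50-marker,
149-offspring cross (~900 simulated markers, ~700 after QC; about 250k
pairwise estimates), and the estimator checks use 500 random pairs against
the grid oracle plus 200 replicates per true recombination fraction. These
sizes give stable Monte-Carlo behaviour while keeping a full run in the
low minutes on one core.

# Known limitations

* Two-point only: no multipoint HMM, no genotype-error correction during
  ordering, no sex-specific maps, no interference-aware (Kosambi) distances.
* Ordering of bins closer than ~1 cM at this family size is reported but
  not meaningful, as discussed above.
* The reference-agreement score used in threshold selection is pairwise
  co-grouping, which is label-free but quadratic in shared contigs; for the
  contig counts involved here that is immaterial.
* `hk` markers carry less information than `fi` markers; groups dominated
  by single-parent markers order less reliably, and a marker whose only
  informative partners are distant can be placed at a group end.
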