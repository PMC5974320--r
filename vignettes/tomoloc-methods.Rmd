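---
title: "Axial localization profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Axial localization profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomoloc)
```

# The problem

A mature amphibian egg is polarized along its animal–vegetal (A–V) axis:
the nucleus and most ribosomes sit near the animal pole, yolk and the germ
plasm near the vegetal pole, and many maternal mRNAs and proteins are
actively localized along this axis before fertilization. Tomographic
profiling cuts the egg into consecutive cryosections, pools them into a few
segments ordered from the animal pole (five segments A–E for RNA-seq, four
segments A–D for proteomics), and measures each molecule's abundance per
segment in several biological replicates. `tomoloc` implements the
downstream analysis of such segment tables: normalization to whole-egg
content, rule-based localization classification, homoeologue (.L/.S)
comparison in an allotetraploid genome, and sequence analysis of 3′UTR
localization elements ("zipcodes").

# Normalization model

Sequencing depth per segment is not proportional to the segment's share of
the egg's RNA: library preparation equalizes input, and yolk-rich vegetal
segments behave differently from animal ones. Median-of-ratios style
normalization assumes most genes are *equally* distributed across samples —
false by construction along an intracellular axis. Instead a small panel of
anchor genes is measured by qPCR tomography on whole eggs. For an anchor
$g$ with quantification cycles $Cq_{g,s}$ per segment $s$, the relative
amount is $q_{g,s} \propto \mathrm{eff}^{-Cq_{g,s}}$ (amplification
efficiency 2 by default, configurable per anchor). Each qPCR replicate is
normalized to sum 1 before averaging so plate offsets cancel. The size
factor of segment $s$ in sequencing replicate $r$ is

$$ f_{s,r} = \operatorname{median}_g \; \frac{q_{g,s}}{r_{g,s,r}}, $$

where $r_{g,s,r}$ is the anchor's observed count fraction, rescaled so the
factors have geometric mean 1 per replicate. The median makes one
misbehaving anchor harmless; anchors with zero counts in any segment are
excluded with a warning. Factors are computed and applied per replicate;
the alternative (pooling replicates before estimation) differs only at
second order and is not exposed.

After normalization, genes with a mean normalized value below 15 across all
segment × replicate cells are removed (strict `<`), per-replicate fraction
profiles are formed, and the consensus profile is the arithmetic mean of
replicate fraction vectors (renormalized), so shallow and deep replicates
weigh equally.

Proteome intensities instead get global-mean normalization: each sample
column is divided by its mean over proteins, equalizing column means — the
standard choice for iTRAQ-style relative intensities when most proteins are
comparable across samples.

# Classification rules

RNA consensus fractions $(p_A,\dots,p_E)$ are assigned by fixed threshold
rules, evaluated with strict inequalities:

* **extremely animal** — strict maximum in A; $(p_A+p_B) > (p_D+p_E)$;
  $p_C > p_D$ or $p_C > p_E$;
* **animal** — strict maximum in B; $p_D+p_E < 0.40$;
* **vegetal** — $(p_D+p_E) > (p_A+p_B+p_C)$; $p_D$ exceeds at least one of
  $p_A, p_B, p_C$;
* **extremely vegetal** — $p_E > 0.50$ and $p_E > 2\,p_D$;
* **other** — none of the above.

An extremely vegetal profile necessarily also satisfies the vegetal rules,
so precedence is extremely vegetal → extremely animal → vegetal → animal →
other; all other rule pairs are mutually exclusive (animal requires
$p_D+p_E<0.4$ while vegetal implies $p_D+p_E>0.5$, and two different
segments cannot both be the strict maximum). A property test samples the
5-simplex and asserts that only the vegetal pair ever co-fires. Ties (flat
profiles) fail every "strict maximum" clause and land in *other*, which is
exactly the catch-all's role. The "40%/50% of all transcripts" thresholds
are fractions of that gene's transcripts across the five segments, so
classification is scale-invariant.

The grammatically ambiguous clauses "C > D or E" and "D > A or B or C" are
read as disjunctions of pairwise comparisons (not comparisons against a
maximum); this is the weaker and more inclusive reading and is applied
consistently.

Protein profiles $(p_A,\dots,p_D)$ use: **animal** — strict maximum in A
and $p_A - p_D > 0.05$ (fraction scale, i.e. five percentage points);
**even** — every segment within $[0.20, 0.30]$ with relative standard
deviation (sd/mean) below 5%, *or* strict maximum in B with $p_C > p_D$
(the protein echo of the animal mRNA profile); **vegetal** — the larger of
$p_C, p_D$ exceeds both $p_A$ and $p_B$ with a margin over $p_A$ above
0.05. Precedence animal → even → vegetal → other. Proteins are classified
per replicate and a label must be shared by at least 2 of 3 replicates
(`consensus_category()`); RNA is classified on the consensus profile by
default, with per-replicate + quorum available behind a function.

# k-mer over-representation

For a category's 3′UTR set, the observed count $O_g$ of a k-mer in gene $g$
counts overlapping forward-strand windows (maternal mRNA is
single-stranded; nothing in the package scans reverse complements). The
expected count under a uniform-composition random-sequence model with
repeat parameter $t$ is

$$ E_g = \binom{N_g - t(k-1)}{t} \big/ 4^{tk}, $$

which for the default $t = 1$ is $(N_g-k+1)/4^k$. The test statistic is the
goodness-of-fit form $x^2 = \sum_g (O_g-E_g)^2/E_g$ with $df = n-1$ genes,
upper-tailed, significant at raw $p < 0.001$ **and** $\sum O > \sum E$
(over-representation only; a two-sided test would also flag depletion).
No multiple-testing correction is applied across the $4^k$ k-mers — the
screen is deliberately run at a raw threshold, which is a caveat to keep in
mind when reading absolute counts of significant k-mers. Genes shorter than
k are excluded from that k's statistic.

Two properties of this *printed* recipe deserve attention. First, treating
genes as cells with $df = n-1$ ignores that $E_g$ varies and that
overlapping window counts are dependent; second, for small $E_g$ the
per-gene terms are strongly right-skewed. `kmer_null_calibration()`
measures the consequence: with 10 genes of 300 nt and a non-self-overlapping
5-mer, the empirical rejection rate at nominal $\alpha = 10^{-3}$ is about
$4\times10^{-2}$ — roughly forty-fold anticonservative, driven almost
entirely by the occasional gene with 3+ chance occurrences. The recipe is
therefore a *screen*, not a calibrated test; the planted-signal recovery
experiments below show it still separates real signal cleanly, and the
uniqueness filter (significant in exactly one category group) removes most
of the shared background. The "animal" group for uniqueness is the
extremely-animal UTR set and the "vegetal" group is the union of vegetal
and extremely vegetal UTRs, mirroring the set sizes used for motif
discovery. An optional composition-adjusted expectation (product of
observed base frequencies) exists but is off by default, matching the
uniform-$A=4$ model above.

# Motif scanning and enrichment

IUPAC consensus motifs are matched exactly: a window matches when every
position's base belongs to the column's IUPAC set; overlapping matches are
all reported; positions are 0-based, half-open, forward strand only. PWMs
are scanned by log-odds scores $\log_2(p_{b,j}/\mathrm{bg}_b)$ with
pseudocount $10^{-4}$; the match threshold for a p-value level is exact:
the null distribution of window scores is built by dynamic programming
(per-column score masses convolved under the background, scores discretized
at $10^{-3}$ log2 units, both configurable), and the threshold is the
smallest grid score whose upper tail is at most $\alpha$ (0.001 by
default). For widths up to 6 the DP tail is tested against full $4^w$
enumeration at $10^{-9}$ tolerance.

Presence summaries report, per motif and category, the proportion of UTRs
with at least one occurrence (heatmap quantity) and occurrences per kbp
(overlaps counted individually — this affects the per-kbp rate but not the
presence proportion). Category enrichment uses the one-sided
hypergeometric tail (Fisher's exact enrichment p), with Haldane's 0.5
correction for the odds ratio when a cell is zero.

# Motif families

Motifs are compared by ungapped alignment: slide one PWM along the other
(at least 4 aligned columns by default), score each offset by the mean
per-column Pearson correlation, and keep the best. IUPAC motifs are
0/1-normalized into PWMs first. Columns are given a pseudocount of
$10^{-3}$ and the correlation denominator carries an $\varepsilon$
($10^{-12}$) ridge so a constant (uninformative) column contributes a
correlation of 0 rather than NaN — a plain pseudocount cannot break the
constancy of a uniform column. $1 - \text{best correlation}$ is a distance
in $[0,2]$; UPGMA (size-weighted average linkage, heights at half the merge
distance, deterministic lexicographic tie-break) builds the dendrogram, and
cutting at a user height yields families. The familial consensus aligns
each member to the family's widest member at its best pairwise offset and
averages the covered columns. This single align-and-average pass replaces
an iterative profile-refinement loop; for the tight families the cut
produces, the two differ negligibly, and the simpler rule is deterministic.
No default cut height is claimed to reproduce any particular published
family count — family grouping from a dendrogram is ultimately a judgment
call, so the height is an explicit parameter.

# Homoeologues

Allotetraploid gene duplicates carry `.L`/`.S` suffixes (long/short
chromosome). Pairing strips the suffix; two `.L` entries for one base
symbol is an error, unpaired genes are reported rather than dropped. A pair
is *concordant* when both members carry the same localization category and
*diametrically opposite* when one side is vegetal/extremely vegetal and the
other animal/extremely animal. Per-pair motif counts use the exact IUPAC
scanner; when the two categories differ, the count ratio is printed vegetal
copy first (the "3:0" convention).

# The synthetic-data generator

Every analysis stage is exercised on generated data whose structure mirrors
the real experiment; all randomness flows from one seed and regenerating
with the same seed reproduces every table exactly.

* **Categories and profiles.** 2000 genes by default, drawn over the five
  RNA categories at proportions 2.8 / 94.4 / 1.3 / 0.2 / 1.3% (the last is
  the remainder, assigned to *other*). Each category has an archetype
  profile validated against its own rules at configuration time; a gene's
  true fraction vector is drawn from a Dirichlet with concentration 200
  around its archetype and **rejection-sampled until it satisfies its
  category's rules**, so the generated truth is classified-back by
  construction and "true category" is unambiguous. Without this step a
  nontrivial share of draws from the animal archetype would cross the
  strict-maximum boundary into extremely-animal territory and the notion of
  a generating category would dissolve.
* **Counts.** Expected count of gene $g$ in segment $s$, replicate $r$, is
  $\text{abundance}_g \times p_{g,s} \times d_s$ with per-segment
  distortions $d_s$ (all 1 by default) and log-normal abundances
  (meanlog $\log 4000$, sdlog 1.2). Observed counts are negative binomial
  with size 2000. The Dirichlet component carries the biological
  profile variability, so the NB layer models the near-technical counting
  noise of deeply sequenced material; both are configurable, and
  `count_model = "none"` switches to noise-free (observed = expected) for
  exact-recovery experiments. Even so, genes whose true draw lies within
  measurement reach of a rule boundary can flip category under counting
  noise — with these defaults that affects just under 1% of genes, which is
  why recovery-style checks are asserted on results pooled over several
  seeded datasets rather than on a single draw.
* **Anchors.** Ten abundant anchor genes cycle through the categories;
  their Cq values are $-\log_2 p_{g,s}$ plus a per-replicate plate offset
  and N(0, 0.2) cycles of technical noise (a typical qPCR spread;
  `cq_sigma = 0` gives noise-free anchors). Anchor Cq reflects the
  *undistorted* truth — that is the entire point of anchoring.
* **3′UTRs.** iid sequences from the configured base composition,
  log-normal lengths around ~0.9 kb, with Poisson-many copies of a planted
  element (TTCAC, the canonical CAC-rich vegetal zipcode core) inserted at
  uniform non-overlapping positions — rate 2 per UTR in vegetal and
  extremely vegetal genes, 0 elsewhere, by default. Plant positions are
  recorded in the ground truth.
* **Homoeologues.** Half the genes are expanded into `.L`/`.S` pairs; with
  probability 0.03 the S copy is re-assigned to a different category
  (drawn by the remaining categories' proportions) and its profile redrawn.
  The S-copy UTR background is the L background mutated at 1% per base;
  motif planting follows each copy's own category, so discordant
  vegetal/animal pairs acquire asymmetric motif counts.
* **Proteome.** 400 proteins over four segments, archetypes
  animal/even/vegetal validated against the protein rules, log-normal
  multiplicative noise (sdlog 0.05, an optimistic but realistic iTRAQ CV),
  three replicates.

What the generator does *not* emulate: positional autocorrelation or
composition bias in real 3′UTRs, yolk interference, alignment artifacts,
mappability, or length-dependent motif density. Passing the recovery tests
therefore demonstrates the pipeline's correctness on data satisfying its
own assumptions, not performance on any particular real dataset.

# Validation scale and numerical choices

The shipped checks run at desk scale deliberately: classification rule
exclusivity on $10^5$ simplex points; archetype recovery pooled over ten
2000-gene datasets; normalization rescue under distortion
$d = (2,1,1,1,0.5)$ pooled over five (plus one noise-free run asserting
$f_s \propto 1/d_s$ to $10^{-6}$ — it holds to machine precision); null
calibration over $10^4$ simulated categories; planted-motif recovery over
20 seeded runs of 150 vegetal vs 330 extremely-animal 1-kb UTRs; scanner
and clustering oracles by exhaustive enumeration (all $4^w$ words, all
2×2 tables with row margins ≤ 30, 100 random UPGMA instances); and
homoeologue discordance estimation over 20 runs of 1000 pairs. Fractions
are asserted to sum to 1 at $10^{-9}$; classification accepts profiles at
$10^{-6}$. UPGMA ties break lexicographically; PWM scores are discretized
at $10^{-3}$ log2 units with pseudocount $10^{-4}$.

# Known limitations

* The k-mer screen's nominal level is anticonservative (see the
  calibration discussion); treat its absolute significant-k-mer counts as
  screen output.
* The `t > 1` repeat-parameter branch of the expectation model is
  implemented as the binomial-coefficient form but is exercised only by
  unit tests, not by any shipped analysis.
* IUPAC mode reports no per-match p-value (every match is exact); use PWM
  mode when a match-level significance is needed.
* 3′UTRs are ingested as FASTA; delimiting UTRs from a genome annotation
  is upstream of this package and strongly affects absolute k-mer counts.
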