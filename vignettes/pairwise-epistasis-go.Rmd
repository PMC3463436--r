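---
title: "From pairwise epistasis scans to replicated gene-set findings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pairwise epistasis scans to replicated gene-set findings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Single-SNP genome-wide association scans of complex diseases often fail
to produce replicable hits, even when heritability estimates say the
signal must be somewhere. One working hypothesis is that much of the
signal lives in nonadditive joint effects of SNP pairs, individually too
weak and too numerous to survive genome-wide correction, but
concentrated in the genes of particular pathways. pairgo implements an
analysis strategy built around that hypothesis: score every SNP pair
with a model-free interaction classifier, calibrate significance with a
max-statistic permutation null, roll pair evidence up to SNPs, genes and
gene sets, and accept only gene sets that are significant in two
independent case-control cohorts.

```{r setup}
library(pairgo)
```

# The model at each level

## Pair level: MDR accuracy

For SNPs $i$ and $j$ with minor-allele-count genotypes $g \in \{0,1,2\}$,
the $3 \times 3$ joint genotype table is pooled into a one-dimensional
HIGH/LOW attribute: a cell is HIGH risk when its case:control ratio is at
least the sample-wide ratio $T = n_{\mathrm{cases}}/n_{\mathrm{controls}}$.
This is multifactor dimensionality reduction (MDR): a constructive
induction step that makes no assumption about the genetic model, so
additive, dominant and purely epistatic patterns are all visible to it.
The pooled attribute is scored by classification accuracy

$$A_{ij} = \frac{\#\{\text{cases in HIGH cells}\} +
  \#\{\text{controls in LOW cells}\}}{n},$$

computed on the whole sample (no cross-validation: significance is
judged against a permutation null rather than by out-of-sample error).
Individuals missing a call at either SNP are dropped from that pair
only. Cells are compared to $T$ by exact integer cross-multiplication,
so the tie rule (ties are HIGH by default, the classical MDR convention)
is never at the mercy of floating-point rounding. Balanced accuracy is
available via `statistic = "balanced_accuracy"` for unbalanced cohorts;
plain accuracy is the default since the intended cohorts are
near-balanced.

## Genome-wide null: permutation of the maximum

All $\binom{m}{2}$ pairs are scanned exhaustively — the loop runs in
compiled code, which is what makes exhaustive rescanning under hundreds
of label permutations affordable;
$\binom{550{,}000}{2} = 151{,}249{,}725{,}000$ pairs is the scale this
design targets at full size. Because the best pair is selected from an
enormous family, its accuracy is only meaningful against the null
distribution of the *maximum*: case-control labels are permuted $N$
times (default 1000), the full scan repeated on each permuted dataset,
and the best accuracy per permutation recorded. The $1-\alpha$ quantile
of these maxima is the genome-wide critical value $c$, and every model
p-value is

$$p = \frac{1 + \#\{\text{null maxima} \ge A\}}{N + 1},$$

the add-one Monte-Carlo convention, so $p \in (0, 1]$ and is never
exactly zero. Permutation $k$ uses seed $s + k$, making the null
reproducible and embarrassingly parallel. Each cohort gets its own
independent null — critical values differ between cohorts because allele
frequency spectra and sample sizes do.

## SNP, gene and set levels

Each SNP inherits the accuracy and p-value of the best pair containing
it. SNPs are assigned to every gene whose body, extended by
$W = 500$ kb on each side, contains them (inclusive at both ends;
rationale: regulatory variants well outside the transcript can
participate in interactions). Gene-level evidence is then an
over-representation question: among the $M$ SNPs mapped to at least one
gene, $K$ are genome-wide significant at $\alpha$; a gene with $n$
mapped SNPs of which $k$ are significant gets the one-sided
hypergeometric upper-tail p-value

$$p = \sum_{i=k}^{\min(K,n)}
  \frac{\binom{K}{i}\binom{M-K}{n-i}}{\binom{M}{n}},$$

and the same test is applied one level up: genes with $p \le \alpha$
within gene sets, with the universe restricted to genes that were
actually testable (at least one mapped SNP). No within-study
multiple-testing adjustment is applied at either level; instead a gene
set counts as a finding only when $p \le \alpha$ in **both** the
detection and the replication cohort — replication across independent
data is the false-positive control.

# Universe choices

Two universe definitions were genuinely open and are worth stating
plainly:

* **Gene level**: the universe is SNPs mapped to $\ge 1$ gene, not all
  genotyped SNPs. An unmapped SNP can never appear in any gene's draw,
  so including it would deflate $K/M$ and bias every gene's p-value
  downward.
* **Set level**: the universe is observed (testable) genes, not the full
  annotation. A set's "size" should reflect what the data could have
  shown; membership is intersected with the universe before counting,
  and symbols are matched case-insensitively (annotation sources differ
  in capitalization). A set with empty intersection gets $p = 1$ and an
  `untestable` flag rather than an error.

A SNP mapped to several overlapping gene windows counts once in the
universe and once in each such gene's draw: the draws are not a
partition of the universe. This slightly favours genes in gene-dense
regions and is documented as an approximation; windows in the synthetic
data are built disjoint, so the tests are not affected by it.

# The synthetic cohort generator

`make_synthetic_truth()` + `simulate_cohort()` stand in for a pair of
real GWAS cohorts. The defaults emulate the statistical shape of two
modest single-disease case-control studies: a few hundred subjects per
arm (250/250 by default), biallelic SNPs under Hardy-Weinberg
equilibrium with minor-allele frequencies uniform on $[0.05, 0.5]$,
genes of 100 kb laid out so that adjacent $\pm 500$ kb windows never
overlap (each SNP maps to exactly one gene, keeping ground truth
unambiguous), and one gene set collection: a 3-gene target set plus 20
size-matched decoys.

The planted signal is the XOR penetrance model
$f(g_1, g_2) = \beta + \epsilon \cdot [g_1 + g_2 \text{ odd}]$ with
baseline $\beta = 0.1$ and effect $\epsilon = 0.4$ at MAF 0.5: its
single-SNP marginal penetrance is exactly constant, so the pair is
invisible to any marginal test and detectable only by a joint scan —
the cleanest possible probe of the pipeline's reason for existing.
Functional genotypes are drawn by rejection sampling conditional on
case/control status, matching case-control ascertainment.

What the generator deliberately does **not** emulate: linkage
disequilibrium, population stratification, genotyping error and
missingness patterns, and realistic gene/set size heterogeneity.
Passing tests therefore demonstrate the statistical machinery is
correct and calibrated on clean data; they do not demonstrate
robustness to confounding structure in real cohorts.

# Numerical choices and degenerate inputs

* Accuracies are doubles formed from small-integer ratios; all
  $\ge$ comparisons between accuracies use a $10^{-12}$ tolerance,
  orders of magnitude below the attainable spacing. HIGH/LOW cell
  decisions are exact integer arithmetic.
* Pairs where one class disappears after pairwise-complete deletion are
  recorded with accuracy 0 and flagged degenerate, never silently
  included; a SNP with no valid pair gets p-value 1 and a flag.
* When no null maximum has tail mass $\le \alpha$ (e.g. all maxima
  identical), `critical_value()` returns a sentinel above the largest
  maximum with `attained = FALSE` instead of pretending a threshold
  exists.
* BED input is converted to 1-based inclusive coordinates at the
  boundary and back on write; everything internal is 1-based inclusive,
  which keeps the window rule $start - W \le pos \le end + W$ free of
  off-by-one cases (both boundary SNPs are mapped, tested explicitly).

# Calibration and the tie structure of permutation p-values

A property worth understanding before trusting any permutation p-value
from a discrete statistic: with a few hundred subjects the accuracy
grid is coarse ($1/n$), and the scan maximum concentrates on a handful
of grid values — on the default null conditions (100 SNPs, 100
cases/100 controls, $N = 200$) about 16 distinct values with modal mass
around 0.2. The conservative convention
$p = (1 + \#\{\text{maxima} \ge A\})/(N+1)$ then ties heavily: $p$ is
*valid* (never anti-conservative, which the acceptance suite checks
directly at several levels) but provably super-uniform, so a
Kolmogorov-Smirnov test of $p$ against the continuous uniform would
reject for any correct implementation. The suite therefore applies the
KS uniformity check to the randomized-PIT form of the same quantity,
$(\#\{> A\} + U \cdot (1 + \#\{= A\}))/(N+1)$ with
$U \sim \mathrm{Unif}(0,1)$, which is exactly uniform under
exchangeability — the standard KS construction for discrete p-values.
The p-value the pipeline reports remains the conservative one.

# Problem sizes used in the test suite

The statistical validation runs at sizes chosen to make the Monte-Carlo
assertions sharp while keeping an exhaustive permutation scan per
replicate affordable: oracle equivalence on 100 random studies of up to
30 SNPs; null calibration on 200 cohorts of 100 SNPs (100/100,
$N = 200$); replication-level false positives on 50 null cohort pairs;
planted-signal recovery on 25 detection/replication pairs of 500 SNPs
(200/200, $N = 100$), requiring the target set to replicate in at least
80% of pairs with no decoy above 20%. At those sizes the compiled scan
keeps the whole suite in a few minutes on one core.

# A small end-to-end run

```{r, eval = FALSE}
truth <- make_synthetic_truth()            # 500 SNPs, XOR pair planted
det <- simulate_cohort(truth, 200, 200, seed = 1)
rep_ <- simulate_cohort(truth, 200, 200, seed = 2)
res <- run_cohort_pair(det$study, rep_$study, truth$snp_map,
                       truth$genes, truth$sets,
                       n_permutations = 100, seed = 3)
head(res$replication_table)
```

# Known limitations

* Order-2 interactions only; higher-order MDR models are out of scope.
* Whole-sample accuracy with a permutation null, not cross-validated
  MDR; the two agree on strong signals but are not interchangeable.
* The gene-level test assumes genes driving pathway signal carry
  *several* significant SNPs; pathways made of genes with one
  significant SNP each will be missed.
* No LD-aware pruning: in real data, LD can make many SNPs in one
  region significant together and inflate a gene's $k$ — another reason
  replication, not the within-study p-value, is the decision criterion.
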