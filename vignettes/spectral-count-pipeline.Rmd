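---
title: "Tiered differential expression from spectral counts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered differential expression from spectral counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsafDE)
```

## The problem

Label-free shotgun proteomics commonly quantifies proteins by spectral
counting: the number of MS/MS spectra matched to a protein in a run (SpC) is
a proxy for its abundance. Comparing two groups of runs — for instance sperm
samples from cancer patients against proven-fertile donors — then requires
(i) a normalization that makes counts comparable across runs and protein
lengths, (ii) a decision rule for when a protein is differentially
expressed, and (iii) a pathway-level summary of the resulting protein lists.
`nsafDE` implements this stack for the tiered-threshold procedure used in
spectral-counting studies, together with a simulator that provides ground
truth for validating every stage.

## NSAF quantification

Longer proteins yield more tryptic peptides and hence more spectra at equal
molar abundance, and total spectral yield varies between runs. The
normalized spectral abundance factor corrects both: for protein $i$ with
length $L_i$ (residues) in run $r$,

$$\mathrm{NSAF}_{i,r} = \frac{\mathrm{SpC}_{i,r}/L_i}
{\sum_j \mathrm{SpC}_{j,r}/L_j},$$

so each run's NSAF values form a composition summing to 1. Two consequences
are load-bearing for the tests: NSAF is invariant to rescaling all counts in
a run, and at equal counts the longer protein gets strictly less NSAF.

NSAF is computed per run and then averaged arithmetically within each group,
rather than on counts pooled across runs: preserving run-level values is
what makes a replicate-based statistical test possible. A run with zero
total counts has no defined normalization; such runs are flagged and
excluded from group means with a warning rather than imputed.

## The tiered caller

Spectral counts are noisy at low abundance, so a single global threshold
either floods the low-abundance range with false calls or wastes power at
high abundance. The procedure therefore assigns each protein an abundance
tier from its mean SpC and applies tier-specific thresholds (`tier_rules()`):
very low [1.7, 8) with $p \le 0.001$ and NSAF ratio $\ge 2.5$ / $\le 0.4$;
low [8, 20) with $p \le 0.01$ and the same ratios; medium [20, 80) with
$p \le 0.05$, $\ge 2.0$ / $\le 0.5$; high [80, $\infty$) with $p \le 0.05$,
$\ge 1.5$ / $\le 0.67$. The published bins are printed as integer ranges
("1.7–7", "8–19", ...), which leaves gaps for fractional means; we close
them as contiguous half-open intervals, which agrees with every printed
integer and makes tier assignment total. The tier is assigned from the
larger of the two group means: a protein well measured in either group
should be judged at that evidence level.

The fractional lower edge (1.7) implies mean SpC over runs, and doubles as
the detection floor: a protein is *uniquely expressed* in a group when its
mean SpC reaches 1.7 there and is exactly zero in the other group — absence
read literally. A protein detected in one group but with a nonzero
sub-threshold trace in the other is compared statistically, not called
unique. Proteins under the floor in both groups are below detection.

The statistical test is deliberately pluggable, because tiered-threshold
studies rarely name one. The default is Welch's unequal-variance t-test on
$\log(\mathrm{NSAF} + p_0)$ with $p_0$ set to half the smallest nonzero NSAF
in the experiment — the log stabilizes the strong mean–variance relationship
of compositional abundance data, and the pseudocount keeps zeros finite.
Fisher's exact test on group-pooled counts (protein vs all other spectra) is
available as `test = "fisher_pooled"` for designs where replicate-level
variance cannot be estimated. When both groups are exactly constant the t
statistic is undefined; we return $p = 1$ when the constants agree and 0
otherwise. No multiple-testing correction is applied: the procedure controls
errors only through its tiered per-test bounds, which is a known caveat of
this method family and the main reason the simulator reports an empirical
FDR.

A protein present in both groups is then overexpressed if
$p \le p_{\max}(\text{tier})$ and ratio $\ge$ the tier's over bound,
underexpressed if $p \le p_{\max}$ and ratio $\le$ the under bound, else
unchanged (all thresholds inclusive, as printed); unique proteins
short-circuit past the test, since no ratio is defined across a presence
gap. The partition obeys two accounting identities checked property-style in
the tests: DEPs = over + under + unique(test) + unique(reference), and
common = over + under + unchanged.

## Pathway layer

Over-representation of a gene set in the DEP list is the hypergeometric
upper tail $P[X \ge k]$ with the *detected* proteins as the universe — using
the whole proteome would reward detection bias, though the universe is a
parameter. Directional sets (signed regulator–target annotations, supplied
as a sidecar to standard GMT files since GMT has no signed extension) get
the additive activation z-score

$$z = \frac{n_{\text{consistent}} - n_{\text{inconsistent}}}
{\sqrt{n_{\text{consistent}} + n_{\text{inconsistent}}}},$$

a member being consistent when its observed direction (over $\to +1$, under
$\to -1$) matches its expected direction under activation. Uniquely
expressed proteins contribute observed signs by default ($+1$ in the test
group, $-1$ in the reference), since presence/absence is the strongest
direction evidence spectral counting offers; `include_unique = FALSE`
disables this. The prediction rule is strict: $z > 2$ activated, $z < -2$
deactivated, anything else — including exactly $\pm 2$ and undefined scores —
no prediction. Published tables sometimes list pathways at exactly $-2.00$
among deactivated ones; under the strict printed rule that value yields no
prediction, and we keep the strict rule. $|z| \le \sqrt{m}$ over $m$
scoreable members, with equality only for fully consistent (or fully
inconsistent) sets — so small sets can never clear the threshold with fewer
than five scoreable members.

## The simulator and what it does (not) show

`simulate_dataset()` emulates the targeted study design: two groups, three
runs per group (pooled biological samples run on gel), protein lengths
uniform on 100–2000 residues, baseline expected counts $\mu_i$ log-normal
(meanlog $= \log 4$, sdlog $= 1.1$), and counts
$\mathrm{SpC}_{i,r} \sim \mathrm{NB}(\mu_i f_{i,g},\ \theta = 5)$ — negative
binomial rather than Poisson because between-run biological and pooling
variability overdisperses real spectral counts. The log-normal parameters
put the bulk of detected proteins in the very-low tier, mirroring the
strongly right-skewed abundance distributions these experiments report. By
default 5% of proteins are overexpressed and 5% underexpressed at fold
change 4, and 2% are unique to each group ($f = 0$ in the absent group). One
global seed drives all randomness.

Two honest limitations. First, pooling is not modeled explicitly — the
simulator draws runs directly, so donor-level variance collapsed by pooling
is folded into $\theta$. Second, it simulates neither peptides nor protein
inference, so identification errors (shared peptides, one-hit wonders) are
outside what passing tests demonstrate about real data.

`evaluate_recovery()` compares calls to truth: pooled sensitivity and FDR
over the over/under/unique classes, and unique-protein sensitivity among
unique-truth proteins whose present-group mean SpC reaches the detection
floor (the rest are undetectable by construction). On the frozen seed-42
design, unique proteins are recovered essentially perfectly, while pooled
over/under sensitivity is only ≈ 0.29 at FDR ≈ 0.09: with $n = 3$ replicates
a Welch test almost never reaches $p \le 0.001$, so the very-low tier —
where most proteins live — is close to powerless for common proteins. That
is a property of the published procedure, not of this implementation, and
the frozen test bands record it rather than hide it.

## Numerical and design choices

* Problem sizes in the tests: 500-protein frozen dataset, 1000 small random
  matrices for the NSAF invariants, exhaustive hypergeometric enumeration up
  to $N = 12$, 200 seeds for z antisymmetry — chosen to exercise each
  property densely while keeping the default suite quick to run.
* Tier boundaries are compared with `>=`/`<` on doubles; the rule set
  validator enforces contiguity to $10^{-12}$ and over-bound $> 1 >$
  under-bound in every tier, so the caller is total on valid rules.
* Ties: enrichment tables sort by p-value ascending, then set name, so
  output files are byte-identical across runs; all writers format floats
  explicitly for the same reason.
* Identifiers are opaque case-sensitive strings throughout — mixed UniProt
  accessions and gene symbols both occur in practice and are never
  harmonized silently.
* Degenerate inputs: empty DEP lists give $p = 1$ everywhere and no
  activation predictions; empty set–analysis intersections yield header-only
  heat-map exports with a warning; zero-total runs are excluded from means.
* The command-line layer maps condition classes to exit codes (0 success,
  2 usage/config, 3 data format, 4 internal contract violation) so shell
  pipelines can distinguish user error from data error.

## Known limitations

No multiple-testing correction (by design, see above); no paired designs;
no peptide-level or spectral-index variants (SIN, emPAI, dNSAF); the
pathway layer re-implements only the additive z-score, not causal-network
algorithms; and gene-set knowledge bases must be supplied by the user — the
packaged toy sets exist for tests and documentation only.
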