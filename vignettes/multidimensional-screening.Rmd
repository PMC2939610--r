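---
title: "Multidimensional candidate-gene screening: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional candidate-gene screening: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`multiscreen` screens case-control SNP data for candidate disease genes in
three successive dimensions — genetic association, protein structure, and
functional annotation — and compares the result with a traditional
Fisher/Bonferroni genome-wide association (GWAS) baseline. The premise is
that complex-disease risk is spread over many genes of modest effect, which
a family-wise-corrected significance threshold discards; an inclusive
association screen followed by biological-similarity filters can retain
them. This vignette explains each model, the tunable parameters and their
defaults, the synthetic-fixture generator used for validation, and the
numerical and design choices a maintainer should know about.

## 1. The Bayes-factor association screen

For one SNP, the data are the 2×3 table of case/control counts over
genotypes AA/AB/BB: counts $n_{jA}$ (cases) and $n_{jU}$ (controls) for
genotype $j = 0, 1, 2$, with totals $n_A$ and $n_U$. We take the
prospective view — genotype fixed, case status random. Under the null
$H_0$, every individual is a case with one shared probability $\theta$;
under $H_1$ each genotype has its own $\theta_j$. With independent
Uniform(0,1) priors, both marginal likelihoods are Beta functions of the
counts, and the combinatorial constant cancels in the ratio:

$$
\mathrm{BF} \;=\;
\frac{\prod_{j=0}^{2} B(n_{jA}+1,\; n_{jU}+1)}
     {B(n_A+1,\; n_U+1)},
\qquad
\mathrm{BFLn} = \ln \mathrm{BF}.
$$

`bfln()` evaluates this in log space through `lbeta()` (log-gamma), never
forming a factorial: counts in the hundreds of thousands stay finite.
A SNP supports association when $\mathrm{BFLn} > 0$, strictly — a table
concentrated in a single genotype gives $\mathrm{BFLn} = 0$ exactly and is
*not* called significant. Useful identities, all tested: the score is
invariant under swapping the case and control rows and under permuting the
three genotype columns, and $E[\mathrm{BF}] = 1$ when tables are generated
under the marginal null (shared $\theta \sim U(0,1)$), which the suite
verifies by exact enumeration over all tables at fixed margins. A caution
for Monte-Carlo work: the distribution of BF under that null is extremely
heavy-tailed (at margins 40/40/40 the exact second moment is
$\sim 2 \times 10^{25}$), so a sample mean of BF over any feasible number
of simulated replicates sits well below 1 with near certainty — the
enumeration identity, not a simulated mean, is the sound check of
calibration.

**Quality control.** Before scoring, `qc_filter()` applies three standard
rules, each configurable: minor allele frequency (pooled cases+controls)
below `min_maf` (default 0.01); total genotyped count below `min_call`
(default 0.95) of the cohort size (a call-rate proxy; the cohort size
defaults to the largest total across SNPs); and departure from
Hardy-Weinberg equilibrium in *controls*, tested by the 1-df chi-square
goodness of fit, rejecting at p below `max_hwe_p` (default $10^{-6}$).
These thresholds are conventional GWAS practice; the HWE test uses controls
only because cases may legitimately depart under association. A SNP with no
controls skips the HWE rule and is noted, not dropped.

## 2. The genetic screen: SNP→gene mapping and disease loci

`assign_snps_to_genes()` assigns each SNP to the gene containing it, else
to the nearest gene on the same chromosome within `max_distance` (default
500 kb — the scale within which most enhancers/repressors and linkage
blocks act). Distance is to the nearest interval boundary (0 inside); ties
go to the lexicographically smallest gene id, so results are independent of
input order and of any seed. SNPs farther than the window from every gene
are discarded. Each SNP maps to at most one gene; multi-gene assignment is
out of scope.

`genetic_screen()` then forms the *test set*: genes with at least one
significant SNP **and** interval overlap (any shared base, via
`GenomicRanges`) with at least one disease locus. Overlap rather than
containment is deliberate: disease loci are band-level intervals and
containment would drop boundary genes. Coordinates are 1-based inclusive
internally; BED input/output (0-based half-open) is converted at the
boundary by `rtracklayer`.

## 3. The structural screen: 28 features and the SVM ensemble

Each protein is a 28-dimension physicochemical vector: dims 1–20 the
amino-acid composition in fixed alphabetical one-letter order
(ACDEFGHIKLMNPQRSTVWY), dims 21–26 the crystallographic unit-cell lengths
(Å) and angles (degrees), dim 27 the helical and dim 28 the beta-sheet
fraction. Dims 21–28 are called the "secondary" block (the name is kept
although 21–26 are unit-cell parameters, not secondary structure).
Non-standard residues are excluded from the composition numerator and
denominator and tallied. Helix/sheet values above 1.5 on input are read as
percentages and divided by 100, so either unit is accepted without silent
error. Proteins without a crystal record keep NA in the secondary block
(flagged in a missing mask) and are mean-imputed at standardization;
a strict mode drops incomplete training rows instead.

Features mix units (fractions, Ångströms, degrees), and RBF-kernel
classifiers are scale-sensitive, so all training applies per-dimension
z-scaling with mean and *population* (divide-by-n) standard deviation
estimated on training data only; a zero-variance dimension maps to 0.

The classifier is the libsvm RBF support vector machine (`e1071::svm`)
with the conventional defaults `C = 1`, `gamma = 1/28`. Because the
non-disease space is too diverse to sample once, training uses randomized
sets: all known disease genes plus an equal-size uniform draw from the
negative pool (genes outside every disease locus, minus positives and test
genes). `cross_validate()` evaluates a training set by seeded shuffling
into n folds (default 5), pooling TP/TN/FP/FN across held-out folds, and
reporting sensitivity $Q_p$, specificity $Q_n$ and accuracy $Q_a$;
`evaluate_feature_sets()` repeats this over many randomizations for the
8-dim and 28-dim blocks and summarizes $Q_a$ (min/max/mean/sd). Pooling
(rather than per-fold averaging) is used because pooled counts remain
well-defined even when a small fold lacks one class.

`ensemble_predict()` labels every test gene with each randomized
classifier; a gene is a candidate only if positive in at least
`keep_fraction` of randomizations — the default 1.0 is the strict
intersection, with the fraction exposed as a principled relaxation. The
mean signed distance to the separating hyperplane is reported as a
disease-likeness score. Per-randomization seeds derive from the master
seed by counter (`seed + i`), making the whole ensemble bit-reproducible.
The feature scaler is estimated once on the two training pools, not per
randomized subset: a per-subset scaler adds estimation noise to every
vote while conveying no information, and a single pass mirrors the usual
practice of scaling a dataset once before SVM training.

## 4. The functional screen

Known disease genes are annotated in three namespaces — PIRSF protein
families, GO terms, KEGG pathways (GMT files, read via `fgsea`). A category
of size $n$ in a universe of $N$ genes containing $K$ disease genes, $k$ of
them in the category, is *enriched* when the one-sided hypergeometric tail
$P(X \ge k)$ is at most `alpha` (default 0.05) and $k \ge$ `min_overlap`
(default 2). "Enriched" is not given a formal definition by the screening
idea itself; the hypergeometric over-representation test is the standard
reading. No multiple-testing correction is applied by default because the
screen is deliberately inclusive (Benjamini-Hochberg is available via
`p_adjust`); the looser membership reading (any category holding at least
one disease gene) is recoverable with `alpha = 1, min_overlap = 1`. The
universe defaults to all genes of the catalog.

Each candidate then gets indicators $f_{\mathrm{PIRSF}}, f_{\mathrm{GO}},
f_{\mathrm{KEGG}} \in \{0,1\}$ — annotated to at least one enriched
category in that namespace — and the final indicator is their logical OR.
Candidates with $f = 1$ are the final predictions. Genes absent from all
catalogs get $f = 0$: absence of evidence cannot demonstrate similarity,
the conservative choice.

## 5. The GWAS baseline

`to_allelic()` collapses each genotype table to the allelic 2×2 (each
individual contributes two alleles); `fisher_exact()` computes the
two-sided exact p by summing hypergeometric point probabilities at most
that of the observed table (with the conventional $1+10^{-7}$ relative
tie tolerance), clamped to 1; a zero margin gives p = 1. The allelic
reduction is standard GWAS practice; the 2×3 exact test is out of scope.
`bonferroni_screen()` uses `alpha / n_tests` or a user-supplied literal
threshold — the literal mode exists because published thresholds do not
always equal any obvious `alpha / n` (a reported genome-wide cutoff of
1.835e-8, for instance, matches neither 0.05 nor 0.01 over the tested SNP
count), and reproducing a printed analysis requires accepting the printed
cutoff. `compare_methods()` reports set sizes, intersection and Jaccard
index between the multidimensional and baseline gene sets.

## 6. The synthetic-fixture generator

Every input is generated with known truth, so all stages are testable
offline.

* **Genotype counts** (`simulate_genotype_counts`): genotypes follow
  Hardy-Weinberg proportions at allele frequency p; each individual is a
  case with probability $\theta_j$ given genotype $j$ (causal SNPs) or a
  shared $\theta$ (null SNPs). Tabulation uses the equivalent binomial
  draws. A marginal-null mode fixes genotype margins and draws one shared
  $\theta \sim U(0,1)$ per SNP — the design under which $E[\mathrm{BF}]=1$.
* **Toy genome** (`simulate_genome`): non-overlapping genes, a gene-free
  tail per chromosome so far-from-gene SNPs exist, disease loci built as
  runs of consecutive selected genes padded only into flanking intergenic
  gaps (so exactly the selected genes overlap loci), and SNPs placed
  inside/near/far from genes in stated proportions. Truth records locus
  membership and intended SNP→gene assignments.
* **Protein features** (`simulate_protein_features`): class-conditional
  Gaussians over the 28 dims; compositions floored and renormalized to the
  simplex, lengths/angles/fractions clipped to their ranges. `separation`
  is the total mean shift in per-dimension sd units, spread over
  `signal_dims` with alternating sign — a same-sign shift on all
  composition dims would largely cancel in the renormalization.
  `features_to_files()` converts vectors to a FASTA (sequences sampled
  from the composition, length 1000 by default, chosen so multinomial
  recomposition noise is small against the class sd) plus a crystal TSV.
* **Annotations** (`simulate_annotations`): designated disease categories
  receive each co-clustering gene with probability `clustering_strength`
  on top of uniform background annotations; strength 0 is an exchangeable
  null under which enrichment p-values are calibrated.

The `endtoend` preset wires these together: 2,000 SNPs, 200 genes, 5 loci
covering 40 genes, 20 planted causal genes (effect
$\theta = (0.3, 0.5, 0.7)$, cohort 900 cases / 1,200 controls), feature
separation 4, annotation clustering 0.95. The known-disease-gene set is
sized at 60 — deliberately large relative to the 200-gene toy genome —
because every randomized training set contains all positives, and with
many fewer the per-randomization decision boundary jitters enough that the
strict intersection discards genes the optimal rule classifies positive:
the stability of the published-scale design (hundreds of positives) is
part of what the fixture must emulate. What the generator does **not**
emulate: linkage disequilibrium between SNPs (each SNP is independent),
realistic protein sequences or PDB records, population stratification, GO
graph structure, or gene-length variation. Passing tests therefore
demonstrate correctness of the computations and the screening logic under
the planted model, not performance on real cohorts.

## 7. Problem sizes, determinism and runtime choices

Validation runs at desk scale: the planted pipeline uses 200 SVM
randomizations (config default) rather than the function default 10,000,
and feature-subset evaluation uses tens of randomizations; these sizes
make the full suite run in a couple of minutes while leaving the
published-scale counts one config edit away. All randomness flows from
integer seeds (`withr::with_seed`, counter-derived per-randomization
seeds); `run_pipeline()` writes a JSON report that is byte-identical
across runs of the same config and seed — wall-clock timings go to the
log file, never the report.

## 8. Known limitations

* One gene per SNP; no LD-aware or multi-gene mapping.
* The 2×3 genotype-level exact test is not offered in the baseline.
* No covariate adjustment, imputation, or non-uniform priors on $\theta$.
* Enrichment ignores GO ancestor propagation and pathway topology.
* Proteins with several structures: first record wins, with a message.
* The strict-intersection rule is sensitive to the training pool size;
  `keep_fraction` is the documented relaxation when positives are few.
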