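---
title: "Quantifying mutation accumulation in apomictic lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mutation accumulation in apomictic lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Apomictic plants reproduce clonally through seed: their genomes never
recombine. Two classic population-genetic forces then act against them.
Hill-Robertson interference weakens selection at every site linked to other
selected sites — in a non-recombining genome, that is every site. Muller's
Ratchet removes, irreversibly, the least-loaded genotype class whenever it is
lost by drift. Both predict the same genomic signature: relative to sexual
relatives, asexual lineages should *retain* more derived mutations at sites
under purifying selection.

The signature is confounded by how apomicts arise. In many groups (the
crucifer genus *Boechera* is the canonical diploid case) apomicts are
interspecific hybrids, so each apomict carries one haplotype from the sexual
species under study and one from a diverged sister species — a large load of
"derived" alleles that reflects hybridization, not post-origin mutation.
`apomacc` implements an analysis that separates the two:

1. **Cohort-level constraint contrasts.** Sites are stratified by
   phylogenetic constraint — 0-fold degenerate coding sites, conserved
   coding (CCS) and conserved non-coding (CNS) sites, against 4-fold
   degenerate sites as the neutral reference. For each sample,
   `diversity_summary()` tallies observed heterozygosity
   \(H_0 = n_{het}/n_{polymorphic}\) and substitution rate
   \(D = (0.5\,n_{het} + n_{homalt})/n_{called}\);
   `constrained_neutral_ratio()` forms
   \(d_{constrained}/d_{neutral} = D_{con}/D_{4fold}\), the population-sample
   analogue of \(d_N/d_S\). Mating systems are compared per sympatric pair by
   Fisher's exact test (\(H_0\), \(D\)) and by a one-sided Z test on the
   difference of log odds ratios (the ratios), with
   \(SE = \sqrt{\sum 1/\text{cell}}\).
2. **Hybrid-origin inference.** For each phased apomict haplotype block, a
   five-taxon alignment is built — the two apomict haplotypes (A1, A2), two
   random *pseudo-haplotypes* of the sympatric sexual (S1, S2;
   `make_pseudo_haplotypes()` assigns the two alleles of each heterozygous
   site to the two outputs at random), and the outgroup reference.
   `fit_ml_tree()` evaluates all 15 outgroup-rooted topologies under
   GTR+Gamma by exhaustive search; `classify_topology()` bins the result into
   six classes, of which two (one apomict haplotype basal, the other nested
   with the sexuals) indicate hybrid origin and one (sexuals basal, a
   diverged apomict pair nested) indicates a within-species origin.
3. **Terminal-branch contrasts.** On each hybrid tree the conspecific
   apomict haplotype — the tip closest to S1/S2 by patristic distance
   (`identify_conspecific_tip()`) — accumulated its private mutations
   *after* the origin of apomixis. `assign_branch_mutations()` places derived
   alleles (any base differing from the outgroup state) on branches by
   parsimony; `terminal_contrasts()` compares constrained versus 4-fold
   counts between the conspecific apomict tip and the sexual tips, and
   `branch_length_ratio_test()` tests total terminal-branch counts against a
   conservative 2x null (below).

## The synthetic cohort generator

No raw data accompany the study design this package addresses, so every
stage is validated against `simulate_cohort()`, a seeded generator whose
defaults state the assumed world:

* **8 sympatric pairs** of one sexual and one apomict genotype.
* **Sexuals are highly selfing**: each sexual-lineage mutation is homozygous
  with probability `selfing_F = 0.75` (the reported inbreeding coefficient
  for such populations), heterozygous otherwise — expected heterozygosity is
  depressed by the factor \(1-F\). The lineages are drawn independently from
  the common ancestor; the ancestor's sequence doubles as the outgroup
  reference, so the derived allele is always the ALT allele and polarization
  can be verified exactly.
* **Apomicts are non-recombining hybrids.** A species stem carrying half of
  `hybrid_divergence = 0.02` substitutions/site is shared by all sexuals
  (homozygous) and by the conspecific haplotype of every apomict; each of
  `n_hybrid_origins = 2` hybridization events contributes a sister-species
  haplotype carrying the other half, fixed heterozygous in its apomicts.
  The default of two origins — one shared by all but the last population,
  one private — mirrors the observed structure of apomict complexes in which
  most lineages trace to a small number of hybridizations plus a divergent
  outlier.
* **Post-origin accumulation.** Apomicts sharing an origin are related by a
  seeded coalescent clone genealogy of height `1 - origin_time` lifetimes;
  mutations accrue on *both* haplotypes along its edges. `origin_time = 0.1`
  states that apomixis is old relative to the sampled lineages (apomictic
  alleles are ancient and shared identical-by-descent across the genus), so
  nearly all of an apomict's private load is post-origin. The genealogy's
  internal edges populate the intermediate derived-allele-frequency bins
  that `freq_binned_ratios()` analyzes; founder divergence concentrates in
  the top bin.
* **Selection as retention thinning.** A constrained-site mutation survives
  with probability `retain_constrained_sex = 0.2` in sexual lineages and
  `min(1, relax_factor_rho * 0.2)` in apomicts. `rho = 1` states equal
  selection (the null world); the default `rho = 3` states the relaxed
  purifying selection the method is designed to detect. Placement is
  per-category Poisson, uniform within category runs, infinite-sites
  (positions drawn without replacement), so every cohort site maps to
  exactly one truth-log entry.
* **Rates.** `mu = 0.01` expected mutations/site per lineage lifetime
  matches the per-terminal-branch mutation density seen in resequencing
  contrasts at this divergence scale (order 10^4 mutations per 15 Mb of
  analyzable sequence).

The generator emulates the *statistical* structure the analysis assumes, not
sequencing reality: there are no mapping artifacts, no base-calling errors
(site and genotype qualities are drawn high so the quality filters pass), no
gene conversion, no recombination map in sexuals, and simulated VCFs contain
variant records only. A green simulation test therefore establishes
correctness of the estimators and calibration of the tests under the stated
model — not robustness to alignment error.

## Numerical and design choices

* **Window filter denominator.** The 20 kb / 30%-callable window rule is
  defined against all reference bases of the window, the conservative
  reading when the input is an all-sites genotyper run. Because simulated
  VCFs carry variant records only (callable monomorphic sites are not
  represented), simulation-driven pipelines run `min_callable_frac = 0`; the
  rule itself is exercised by a packaged toy VCF with hand-enumerated
  outcomes. Re-filtering a filtered table reuses the recorded per-window
  callable counts, which makes the filter idempotent.
* **Polymorphic-site denominator of \(H_0\)**: sites segregating across the
  full retained cohort (the pipeline keeps only cohort-polymorphic SNPs),
  with a call in the focal sample.
* **GTR+Gamma fitting.** Base frequencies are set to the empirical
  alignment frequencies (with a pseudocount); the Gamma shape is estimated
  once per alignment by a bounded 1-D search on the provisional best
  topology, after which all 15 topologies are refit; exchangeabilities are
  not free parameters (five-taxon alignments of a few hundred variable
  columns cannot support them). Branch lengths are optimized by
  coordinate-wise Brent search on a log scale in [1e-8, 10], with a fast
  scan of all topologies followed by refinement of the winner to a
  log-likelihood tolerance of 1e-6. Ties break to the lowest canonical
  topology index. For large simulation studies the pipeline offers
  `gamma_k = 1, estimate_alpha = FALSE` (plain GTR) — the generator has no
  within-category rate variation, and the Gamma mixture is validated
  separately against an exhaustive-state oracle.
* **Pseudo-haplotype divergence filter.** Regions whose S1-S2 difference
  proportion is a z > 3 outlier across regions are excluded: elevated
  sexual "heterozygosity" typically marks collapsed duplicates rather than
  single-copy sequence. Bootstrap support (default 100 replicates,
  RAxML-style refitting with model parameters held fixed) must reach 70 on
  both internal edges; alignments shorter than 500 usable columns are
  dropped. None of these three cutoffs is a claim about any published
  analysis — they are configurable defaults.
* **The 2x null of the terminal-branch test.** Sexual pseudo-haplotypes
  split heterozygous mutations between S1 and S2 and send homozygous
  mutations to the shared S1+S2 stem, so under equal accumulation the
  conspecific apomict tip carries at most twice the mutations of the two
  sexual tips *combined*. The test is an exact one-sided binomial on the
  apomict count out of (apomict + summed sexual) against \(p_0 = 2/3\)
  (ratio 2.0 to the summed sexual tips = 4.0 to the per-tip mean). The null
  is exactly attained only when accumulation is mostly heterozygous (low
  selfing); under high selfing it is conservative, which is why the null
  calibration of this test is run at `selfing_F = 0`.
* **Combined Fisher contrast** pools the 2x2 cells of the individual
  contrasts C1-C4 (three contrasts for trees with a sexual cherry, one for
  trees with an apomict haplotype inside the sexual pair). Pooling
  double-counts the apomict cells relative to a stratified
  (Mantel-Haenszel) combination; it is kept as the simplest reading of an
  "overall" exact test and is validated only as such.
* **Frequency-bin denominators.** `freq_binned_ratios()` uses
  bin-restricted numerators over category-wide denominators. Restricting the
  denominators to the bin as well looks natural but cancels the signal
  exactly: conditioning on sites where apomicts carry derived alleles
  equalizes the per-site derived dose across categories and forces every
  ratio to 1. Note also that in the simulated world the per-bin *sexual*
  comparator is degenerate at intermediate bins (independent sexual lineages
  carry no derived alleles at apomict-private sites), so those z values are
  undefined markers; real cohorts with shared polymorphism populate them.
* **Pure class.** Only the topology with basal sexuals and a nested apomict
  pair is called "pure"; the three remaining classes (apomict cherry beside
  a sexual cherry, interleaved pairs, and the mixed pectinate shape) are
  conservatively "ambiguous".
* **Parsimony placement.** Derived mutations are placed on the fixed tree
  by exhaustive enumeration of internal-node states; columns whose minimal
  placement is not unique are discarded and counted, so branch tallies are
  never inflated by arbitrary tie-breaking.

* **Per-pair, not pooled, ratio tests.** `constrained_neutral_ratio()` and
  `odds_ratio_z_test()` operate on per-sample summaries, and the pipeline
  reports the Z test per sympatric pair. Pooling derived-allele counts over
  samples before testing is tempting but statistically wrong in this design:
  a mutation shared through a hybrid origin enters the pooled apomict cells
  once per carrier (seven times for a shared origin), and a species-stem
  substitution enters the pooled sexual cells twice per sexual (homozygous)
  times eight lineages. The pooled cells are then far over-dispersed relative
  to the naive \(\sqrt{\sum 1/\text{cell}}\) standard error and the Z test
  rejects a true null at several times its nominal rate — simulation at
  `rho = 1` shows ~20% rejections for the pooled test versus nominal
  behaviour for the per-pair test. In a single pair each mutation contributes
  one informative count, and shared trunk substitutions appear on *both*
  sides of the contrast, which if anything makes the pair test conservative.

## Known limitations

* The simulator's independent-lineage sexual model has no population
  structure and no shared sexual polymorphism; Fisher/Z tests on real data
  additionally face non-independence among sites (linkage), which the
  simulation's infinite-sites model understates.
* `D` uses callable-base denominators reconstructed from the annotation and
  retained windows; with variant-only input the monomorphic callable count
  is exact only if the window set is.
* The within-species origin mode is a stylized contrast case (deep shared
  polymorphism between the founder and one sexual haplotype lineage), built
  to test that the classifier does *not* call hybrids — not a calibrated
  model of autopolyploid or intraspecific apomict formation.
* Gene conversion, which can erode the heterozygosity signal in real
  apomicts, is outside the generator and the analysis.

Every empirical number quoted in the package's documentation is computed by
the test suite or the README example at run time; the vignette makes no
claims the tests do not check.
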