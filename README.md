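# apomacc

Mutation-accumulation contrasts between sexual and apomictic (asexually
seeding) plant lineages, from multi-sample resequencing data.

## Who this is for

Population geneticists comparing sympatric sexual and clonal genotypes who
want to test the predictions of Muller's Ratchet and Hill-Robertson
interference: that non-recombining lineages retain more derived mutations at
sites under purifying selection. The package covers the full analysis path —
SNP filtering, constraint-stratified diversity statistics, hybrid-origin
inference from five-taxon haplotype trees, and terminal-branch mutation
contrasts — plus a seeded cohort simulator with a complete truth log so every
stage is testable without raw sequencing data.

## The statistics at its core

For each sample and annotation category (0-fold, 4-fold, conserved
non-coding CNS, conserved coding CCS, other):

* observed heterozygosity  H₀ = n_het / n_polymorphic
* substitution rate        D = (0.5·n_het + n_homalt) / n_called
* constraint ratio         d_constrained/d_neutral = D(constrained) / D(4-fold)

Mating systems are compared per sympatric pair with Fisher's exact test
(H₀, D) and a one-sided Z test on log-odds-ratio differences
(d_constrained/d_neutral), with SE = sqrt(Σ 1/cell).

Hybrid origin is inferred per phased apomict haplotype block from the
maximum-likelihood tree (GTR+Γ, exhaustive search over all 15 outgroup-rooted
topologies) of {A1, A2 apomict haplotypes; S1, S2 sexual pseudo-haplotypes;
outgroup}. Topologies with one apomict haplotype basal and the other nested
with the sexuals indicate hybrid origin. On hybrid trees, derived mutations
are placed on branches by parsimony; the terminal branch of the
conspecific-derived apomict haplotype (the one closest to S1/S2) is compared
with the sexual terminal branches by exact 2×2 contrasts of constrained vs
4-fold mutation counts, and by an exact binomial test against the
conservative 2× null (p₀ = 2/3) for total terminal counts.

## Worked example

Simulate an eight-pair cohort with 3-fold relaxed retention of
constrained-site mutations in apomicts, and run the full pipeline:

```r
library(apomacc)

cfg <- pipeline_config(
  sim = list(genome_length = 1e6, relax_factor_rho = 3,
             n_blocks = 12, block_bp = 2000),
  bootstrap_reps = 0,          # skip bootstrap for a quick run
  estimate_alpha = FALSE, gamma_k = 1,
  seed = 11, out_dir = "apomacc_demo")
rep <- run_pipeline(cfg)

rep$H0
rep$cohort_ratio_tests
subset(rep$contrasts, contrast == "combined")
rep$ratio_test[c("ratio", "p_value")]
```

which prints (seed 11):

```
apomict     sexual 
0.21855563 0.01322738 
  constrained ratio_apomict ratio_sexual        z       p_value
1       0fold     0.3774346    0.2037515 31.55788 6.990572e-219
2         CNS     0.3908684    0.2118123 24.86124 9.772542e-137
3         CCS     0.3810052    0.1830603 24.42506 4.633045e-132
  contrast n_trees apo_constrained apo_neutral sex_constrained sex_neutral
5 combined     288             228         294              24          54
  odds_ratio        se    p_value
5   1.744898 0.2607154 0.03627194
$ratio
[1] 3.663594

$p_value
[1] 3.144753e-32
```

Reading the output: apomicts are far more heterozygous than the selfing
sexuals (H₀); the apomict d_constrained/d_neutral ratio exceeds the sexual
one at all three constrained categories — the planted ρ = 3 signal. (The
cohort-level table pools counts over samples and is descriptive; the
calibrated per-pair Z tests are written to `pair_tests.tsv` — see the
vignette on pseudo-replication.) The combined terminal-branch contrast shows the
conspecific-derived apomict haplotype accumulating constrained-site mutations
in excess of the sexual tips (odds ratio > 1), and its total terminal
mutation count rejects the conservative 2× null (ratio > 2, binomial
P ≪ 0.05). Per-stage tables (diversity, pair tests, windows, distance
network, trees, contrasts) are written under `out_dir`.

With `relax_factor_rho = 1` (equal selection) the same pipeline is a null
calibration run and reports non-significant contrasts; the test suite checks
both directions over 100 simulated cohorts each.

The same pipeline runs from files
(`pipeline_config(vcf=, bed=, fasta=, samples=, blocks=, ...)`), expecting a
multi-sample VCF 4.2 (QUAL, FORMAT GQ), a 4-column category BED, the
outgroup/ancestral FASTA, a tab-separated sample sheet
(population/sexual/apomict) and phased haplotype blocks
(chrom, start, end, hap1, hap2). A command-line entry point is installed at
`inst/cli/apomacc.R`:

```sh
Rscript inst/cli/apomacc.R simulate --config config.json --out cohort/
Rscript inst/cli/apomacc.R run-all  --config config.json --out run/ --seed 7
```

## Vignette

`vignettes/mutation-accumulation.Rmd` documents the model, the generator's
assumptions and defaults, numerical choices (optimizer, filters, tie-breaks)
and known limitations.
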