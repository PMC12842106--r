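# morphdrift

Tests whether complete phenotypic sorting of color morphs across
localities can be explained by neutral genetic drift, using a
mitochondrial gene genealogy as the yardstick. The package was built for
the classic situation in aposematic/mimetic systems: a beetle (or
butterfly, or frog) species shows discrete, geographically segregated
color morphs, yet its neutral markers show shallow, unsorted genealogies.
Are the morphs just drifted local variants, or is selection holding them
apart?

## What it computes

**Slatkin–Maddison s statistic.** For a gene tree whose tips carry deme
(morph) labels, `s` is the minimum number of deme-state transitions over
all assignments of states to internal nodes — unit-cost parsimony of the
deme character, computed exactly on multifurcating trees by a per-node
dynamic program and invariant to rooting. For k demes, complete
reciprocal monophyly gives `s = k − 1`; panmixia pushes `s` toward its
maximum `n − max deme size`.

**Structured-coalescent drift test.** Within a morph tree (star polytomy
by default, or any user-supplied topology) with constant haploid
effective size Ne, lineages coalesce at rate `j(j−1)/(2Ne)` per
generation, pool at population merges, and the root population coalesces
to one lineage (continuous-time Kingman approximation). The test
procedure mirrors the field's standard logic:

1. compute the observed `s` on the mitochondrial gene tree;
2. tune the morph-tree branch length `T` to the largest value at which
   at least 5% of simulated gene trees are still as *unsorted* as the
   data, `P(s ≥ s_obs) ≥ 0.05` — a conservative maximum for the true
   divergence time;
3. divide `T` by four (mtDNA has one quarter the effective size of a
   nuclear autosome) to get the branch length for a hypothetical nuclear
   locus controlling the phenotype;
4. simulate 10,000 nuclear genealogies at that length and ask how often
   sorting as complete as the phenotype's (`s ≤ k − 1`) arises. If that
   frequency is below 5%, drift is rejected.

**Supporting analyses.** Per-morph summary statistics (segregating sites
S, nucleotide diversity π as mean pairwise differences, Tajima's D with a
neutral-coalescent significance test), pairwise Φst with permutation
tests, minimum spanning haplotype networks (union of all MSTs over
haplotype Hamming distances, GraphML export), and the binomial-logit
analysis of deviance for reciprocal-translocation predation experiments
(Type-II likelihood-ratio tests for site, color, and their interaction).

**Synthetic data.** A coalescent sequence simulator (infinite sites
mapped onto a finite alignment, exact S/π bookkeeping) with a
forced-monophyly mode, plus Bernoulli predation-table generators, so the
whole pipeline can be exercised without any downloads.

## Worked example

The four-morph sampling design (Red-Green 11, Green 10, Red 9, Blue 11;
41 sequences) with an observed mitochondrial `s = 19`:

```r
library(morphdrift)
fx <- fixture_study_config()
res <- run_drift_test(s_obs = 19, samples = fx$config, ne = 10000,
                      reps = 10000, seed = 1)
print(res)
#> Drift-vs-selection test
#> observed s = 19 on 41 tips, 4 morphs
#> tuned branch length: 1112.4 generations ( 0.1112 Ne ); tail P(s >= s_obs) = 0.0512 at criterion 0.05
#> nuclear branch length: 278 generations
#> selection test at branch length 278 generations:
#>   min simulated s = 13 over 10000 replicates
#>   P(s <= 3 ) = < 1e-04
#>   neutral drift REJECTED at alpha = 0.05
```

Reading: even granting the morphs the deepest divergence compatible with
the mtDNA (≈0.11 Ne generations), a nuclear locus at a quarter of that
depth never reaches complete sorting in 10,000 neutral simulations
(minimum `s` = 13, far above 3), so drift cannot account for perfectly
sorted color morphs.

The predation experiment, from container-level 0/1 outcomes:

```r
counts <- data.frame(site = rep(c("CerroCordoba", "TermasMalleco"), each = 2),
                     phenotype = c("Red-Green", "Blue", "Blue", "Red-Green"),
                     attacks = c(1L, 12L, 2L, 8L), n = 50L)
deviance_tests(predation_from_counts(counts))
#>         term      chisq df            p
#> 1       site  0.4460093  1 5.042362e-01
#> 2      color  1.2396836  1 2.655320e-01
#> 3 site:color 15.3809454  1 8.786992e-05
```

Attack probability depends strongly on the site-by-color combination
(locally mimetic beetles are spared; translocated ones are attacked)
while neither site nor color matters marginally — the signature of
selection by predators on the local warning pattern.

## Command line

`inst/cli/morphdrift.R` wraps the same functions as subcommands
(`popgen`, `network`, `drift-test`, `predation`, `simulate`), emitting
CSV/GraphML/JSON reports, e.g.:

```sh
Rscript inst/cli/morphdrift.R drift-test --s-obs 19 --ne 10000 \
    --samples "Red-Green=11,Green=10,Red=9,Blue=11" --seed 1 \
    --out drift_test.json
```
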