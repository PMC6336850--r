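# cladecology

Comparative genomics and community ecology of Marine Group II (MGII)
Euryarchaea — uncultivated, globally abundant marine archaea whose biology
must be read entirely from metagenome-assembled genomes. Given a collection
of environmental genomes with quality estimates, a phylogenomic tree,
upstream annotation tables and read-recruitment records, `cladecology`
provides a tested, reusable pipeline to:

1. **Dereplicate genomes by ANI** — fragment-based average nucleotide
   identity (1500 bp windows, k-mer seeded, symmetrized), redundancy
   grouping at ≥ 98.5 % ANI, and representative selection by completeness,
   then contamination.
2. **Delineate subclades** — cut a rooted tree where a clade's stem crosses
   a relative root-distance threshold (default 1.2, normalized by mean
   root-to-leaf depth), gate genomes on ≥ 60 of 120 single-copy markers,
   and verify subclades with > 70 % ANI / > 70 % AAI pair support.
3. **Classify traits by rule** — proteorhodopsin function and spectral
   tuning from the residues at reference positions 97 / 108 / 105
   (D97 + K/E108 ⇒ proton pumping; Q105 blue, M105 green), Na⁺-type
   ATP-synthase c-ring motifs (`LPESxxI` vs `LPETIxL`), extracellular
   peptidases (bitscore ≥ 75 plus localization/signal-peptide logic), the
   archaeal flagellum operon (co-localized FlaH/I/J + flagellin), and
   per-subclade 0–1 occurrence matrices.
4. **Build a pangenome** — all-vs-all protein similarity, minbit filtering
   (`score / min(self scores)` ≥ 0.5), Markov clustering (inflation 2), and
   enrichment calls: core (≥ 70 % of both clades), clade-core (≥ 70 % vs
   ≤ 30 %), subclade-unique (≥ 70 % vs ≤ 10 %).
5. **Profile abundance** — alignment filtering at ≥ 95 % identity and
   ≥ 75 % aligned fraction, per-genome read counts, relative fraction
   `r/R`, RPKM `= (r / (L/10³)) / (B/10⁶)`, and the high/low split at
   0.5 % summed recruitment.
6. **Do the ecology** — Bray–Curtis `Σ|x−y| / Σ(x+y)` distances,
   average-linkage dendrograms cut at < 0.8 (taxa) and < 0.7 (samples) to
   find ecological clusters with elevated RPKM, CCA ordination, one-way
   PERMANOVA (pseudo-F from distance sums of squares, permutation p with
   9999 permutations by default), BH-FDR and Bonferroni corrections, Welch
   t-tests, and the standard environmental bins (temperature, oxygen,
   phosphate, nitrate).

A first-class **synthetic-data module** generates every input with planted
ground truth — genomes evolved along a known tree at controlled Jukes–Cantor
divergence, presence/absence matrices with planted enrichment categories,
proteins embedding the diagnostic residues and motifs, and read counts
driven by log-linear environmental responses — so the whole pipeline is
testable without any downloads.

The package is tidyverse-native: functions take data frames first and
return tibbles, fitted objects have `tidy()` / `glance()` methods, and
result types have `autoplot()` / `plot_*()` companions.

## Worked example

Dereplicate a simulated set of three strains (0.5 % mutual divergence) plus
two diverged outgroups:

```r
library(cladecology)

tr <- ape::read.tree(
  text = "((s1:0.0025,s2:0.0025,s3:0.0025):0.06,o1:0.12,o2:0.2);")
sim <- simulate_genome_set(tr, ancestor_length = 50000, seed = 101,
                           completeness = c(85, 96, 90, 75, 75),
                           contamination = c(1, 0.5, 2, 1, 1))
dereplicate(sim$genomes)
#> # A tibble: 5 × 3
#>   genome group is_representative
#>   <chr>  <int> <lgl>
#> 1 s1         1 FALSE
#> 2 s2         1 TRUE
#> 3 s3         1 FALSE
#> 4 o1         2 TRUE
#> 5 o2         3 TRUE
```

The three strains collapse into one group at the 98.5 % threshold (their
pairwise ANI estimates come out at 99.5, matching the planted 0.5 %
divergence) and `s2` is chosen as representative — it has the highest
completeness (96 %). The outgroups stay separate (ANI ≈ 84 and 78).

Detect a planted warm-water bloom in a simulated community and test it:

```r
g  <- tibble::tibble(genome = paste0("g", 1:10), total_length = 2e6)
co <- tibble::tibble(genome = paste0("g", 1:3),
                     variable = "temperature", beta = 3)
simc <- simulate_community(g, n_samples = 40, depth = 1e5,
                           coefficients = co, seed = 7)
rp <- rpkm(simc$counts, g, simc$manifest)
m  <- tidyr::pivot_wider(rp[c("genome", "sample", "rpkm")],
                         names_from = sample, values_from = rpkm)
m  <- as.matrix(tibble::column_to_rownames(m, "genome"))

ecological_clusters(m)
#> # A tibble: 2 × 7
#>   cluster taxa      samples   n_taxa n_samples block_median elevation
#>   <chr>   <list>    <list>     <int>     <int>        <dbl>     <dbl>
#> 1 A       <chr [3]> <chr [4]>      3         4       0.558      111.
#> 2 B       <chr [3]> <chr [9]>      3         9       0.0803      15.9

bins <- bin_environment(simc$env)
permanova(bray_curtis(m, "samples"), bins$temperature_bin,
          n_perm = 9999, seed = 1)
#> One-way PERMANOVA (40 items, 3 groups)
#>   pseudo-F = 30.1,  p = 1e-04  (9999 permutations)
```

Ecological cluster A is exactly the three planted responders (`g1`–`g3`),
elevated ~100-fold over the global median RPKM in the warmest samples, and
the PERMANOVA on the printed temperature bins rejects at the floor of the
permutation p-value (1/10⁴ with 9999 permutations).

## Learning more

The methods vignette (`vignettes/cladecology-methods.Rmd`) documents the
models and rules, every tunable threshold with its default and rationale,
what the synthetic generators do and do not emulate, and the package's
numerical conventions.
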