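# cypscreen

Bait-gene co-expression screening and substrate-inhibition kinetics for
alkaloid pathway gene discovery in R.

`cypscreen` is for researchers mining de novo transcriptomes of non-model
plants for biosynthetic genes. It implements the comparative workflow that
identified the *C-C* phenol-coupling cytochrome P450 of Amaryllidaceae
alkaloid biosynthesis: transcripts that (i) classify as cytochrome P450 by
protein homology, (ii) co-express with a validated bait gene
(the methyltransferase *N4OMT*) under HAYSTACK-style model matching, and
(iii) have homologs in the bait co-expressing lists of *every* other
assembly at a stringent nucleotide cutoff, are flagged as top-priority
candidates. The package also provides the downstream enzymology:
substrate-inhibition kinetics fitting, catalytic efficiency, and MRM mass
bookkeeping for phenol-coupled products.

## The statistics at the core

**Expression-model matching.** A transcript with tissue profile *v*
matches the bait model *m* when all four criteria hold:

* Pearson *r*(*v*, *m*) ≥ 0.8
* background max(*v*) ≥ 1
* fold change max(*v*) / max(min(*v*), floor) ≥ 4
* two-sided *p* ≤ 0.05, with *t* = *r*·√((*n*−2)/(1−*r*²)), df = *n*−2

With three tissues the *p* criterion dominates: *p* ≤ 0.05 ⇔ *r* ≥ 0.9969.

**Homology.** Exact Smith–Waterman local alignment with affine gaps
(BLOSUM62 11/1 for protein; +1/−2, 5/2 for DNA), scored by Karlin–Altschul
*E* = *K·m·n·e*^(−λS). Protein classification uses *E* ≤ 1e−4,
cross-assembly nucleotide linking *E* ≤ 1e−50 (compared in log10 space).

**Kinetics.** Uncompetitive substrate inhibition,

v = kcat·[E]·S / (Km + S + S²/Ki),

fitted by Levenberg–Marquardt least squares; kcat/Km is the catalytic
efficiency (1/(µM·min)); Ki is reported only when the inhibition term
reduces the residual sum of squares by ≥ 5% versus Michaelis–Menten.

A seeded synthetic-data generator plants one bait-correlated P450
orthogroup among log-normal decoys across five assemblies, so the entire
pipeline is testable without external data.

## Worked example

```r
library(cypscreen)

# five assemblies x 250 transcripts, one planted orthogroup, 50 P450 decoys
ds <- generate_screen_dataset(screen_scenario(seed = 1))
report <- run_screen(ds, screen_config(reference = "narcissus_abyssmira"))
#> narcissus_abyssmira: bait narcissus_abyssmira_t175; 3 of 249 transcripts co-express
#> galanthus_sp_abyssmira: bait galanthus_sp_abyssmira_t006; 6 of 249 transcripts co-express
#> galanthus_elwesii_abyssmira: bait galanthus_elwesii_abyssmira_t227; 1 of 249 transcripts co-express
#> galanthus_sp_trinity: bait galanthus_sp_trinity_t016; 5 of 249 transcripts co-express
#> galanthus_elwesii_trinity: bait galanthus_elwesii_trinity_t135; 7 of 249 transcripts co-express
#> narcissus_abyssmira (reference): 1 co-expressing P450 candidates
#> top-priority candidates (present in 5/5 lists): 1

report[, c("candidate_id", "r", "fold", "p", "n_assemblies_present", "top_priority")]
#>               candidate_id         r     fold          p n_assemblies_present top_priority
#> 1 narcissus_abyssmira_t149 0.9974766 42.43386 0.04523531                    5         TRUE
```

One transcript co-expresses with the bait (r = 0.9975, 42-fold
tissue-specific, p ≤ 0.05), classifies as a P450, and has nucleotide
homologs in all four other assemblies' co-expressing lists — it is the
planted candidate (`ds$truth$planted_ids`).

Fitting a simulated kinetic assay (enzyme 2.5 nM, 12 substrate points in
triplicate, 5% noise):

```r
fit <- fit_kinetics(simulate_rates(kinetic_scenario(seed = 1)),
                    "substrate_inhibition", enzyme_conc = 2.5)
fit
#> kinetic_fit (substrate_inhibition, n = 36 points)
#>   Km   = 1.248 +/- 0.055 uM
#>   kcat = 15.66 +/- 0.25 /min
#>   Ki   = 60.39 +/- 2.7 uM
#>   kcat/Km = 12.5 1/(uM*min); residual SS = 19.5
```

The estimates recover the generating parameters (Km 1.13 µM, kcat
15.0/min, Ki 64.3 µM) within their asymptotic uncertainty; the catalytic
efficiency rounds to ~13 1/(µM·min), marking this the preferred substrate.

Small assay computations:

```r
coupled_product_mz(274.30)          # 272.3  (two-hydrogen loss on coupling)
molar_ratio(2.23, alkaloid_molar_masses[["haemanthamine"]],
            0.246, alkaloid_molar_masses[["galanthamine"]])
#> 8.644187                          # bulb molar ratio, ~8.6-fold
```

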