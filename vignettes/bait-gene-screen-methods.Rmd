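---
title: "Methods: bait-gene co-expression screening and substrate-inhibition kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bait-gene co-expression screening and substrate-inhibition kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypscreen)
```

## The problem

Pathway-gene discovery in non-model plants often starts from a single
validated "bait" gene and the observation that enzymes of one biosynthetic
pathway tend to be co-regulated. The screen implemented here targets the
cytochrome P450 that performs the *C-C* phenol-coupling step of
Amaryllidaceae alkaloid biosynthesis: transcripts of several de novo
transcriptome assemblies (different species and different assemblers) are
matched against the tissue-expression model of the bait methyltransferase
(*N4OMT*), restricted to predicted cytochrome P450s, and then intersected
across assemblies by stringent nucleotide homology. A candidate that
co-expresses with the bait in *every* usable assembly — species and
assembler independent — is a top-priority cloning target. The package also
implements the downstream enzymology: substrate-inhibition kinetics,
catalytic efficiency, and the small mass-bookkeeping computations used to
read phenol-coupling activity out of MRM transitions.

## Expression-model matching

A transcript's tissue profile $v$ (here three tissues: leaf,
inflorescence, bulb) is compared with the bait model $m$ by four
criteria, all of which must hold:

* Pearson correlation $r(v, m) \ge 0.8$,
* background $\max(v) \ge 1$ (the transcript must actually be expressed),
* fold change $\max(v) / \max(\min(v), \text{floor}) \ge 4$,
* two-sided correlation p-value $\le 0.05$.

The p-value is parametric: $t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ degrees
of freedom. With three tissues a permutation test is impossible — the
smallest achievable permutation p is $1/3! \approx 0.167$ — so the
parametric form is the only reading under which the p criterion is
satisfiable at all. Its consequence is worth stating plainly: at $n = 3$,
$p \le 0.05$ requires $r \ge 0.9969$, so the p criterion dominates the 0.8
correlation cutoff. `match_criteria(use_p = FALSE)` disables it.

Two further conventions: correlations are computed on raw abundances by
default (`log_transform` is available but off — the transform choice is a
genuine open question and is exposed rather than decided silently), and
the fold-change denominator is floored at the background cutoff because
published bait models contain entries as small as 0.01 RPM that would
otherwise produce folds of $10^4$ from measurement noise. The bait's own
transcript is excluded from its passing list.

## Homology stages

BLAST-style search is replaced by exact Smith–Waterman local alignment
with affine gaps (no seeding heuristics), which is affordable at the
scales this package addresses (hundreds of transcripts of a few kb).
Protein search uses BLOSUM62 with gap open/extend 11/1; nucleotide search
uses +1/−2 with gaps 5/2 — the defaults of the BLAST era the screen
emulates. Significance is Karlin–Altschul:
$E = K m n e^{-\lambda S}$, with $K = 0.041, \lambda = 0.267$ (protein)
and $K = 0.46, \lambda = 1.28$ (DNA). Edge-effect and composition-based
corrections are out of scope; for the decisions the screen takes
(1e-4 protein classification, 1e-50 nucleotide linking) the E-values are
separated by dozens of orders of magnitude from the decision boundary, so
the uncorrected statistic is adequate. Because 1e-50 underflows nothing —
but scores of near-identical kb-scale alignments underflow $e^{-\lambda S}$
— all cutoff comparisons are done in log10 space (`log10_evalue`).

Peptides are predicted as the longest ATG-initiated ORF over six frames
(open-ended at the 3' end, since assembled transcripts are often
incomplete), a deterministic desk-scale replacement for a trained HMM
predictor. P450 classification is by best hit against a reference P450
set at E ≤ 1e-4; the four consensus motifs (EXXR, PERF-region PXRX,
heme-binding FXXGXRXCXG, oxygen binding (A/G)GX(D/E)TT) are reported as
advisory annotation, not as gates — real phenol-coupling P450s deviate
precisely in the oxygen-binding motif, so motif presence must not filter.

The packaged reference P450 set, P450 template and bait protein are
*synthetic* sequences (generated once with a frozen seed, filenames
suffixed `_synthetic`): the curated 472-sequence plant P450 list the
procedure historically used is external supplementary data. The template
carries the four motifs at realistic positions (oxygen binding near
residue 321, EXXR near 387, PXRX near 430, heme motif near 464).

## The intersection screen

`run_screen()` reproduces the workflow end to end: each assembly's bait
transcript is located as the best protein homolog of the bait reference
(an assembly without one aborts the run, named); each assembly's
co-expressing list is computed; the reference assembly's co-expressing
P450s become candidates; and each candidate's nucleotide sequence is
aligned *against the other assemblies' co-expressing lists only* — not
the whole assemblies — at E ≤ 1e-50. That membership semantics matters:
searching the whole assembly and then testing list membership would
accept paralogs that are expressed but not co-expressed. Best-hit
semantics is used (the alternative, any-hit, differs only when a
co-expressing list contains multiple homologs of one candidate).

A candidate's presence count includes its own reference list, so "present
in five of five" means four cross-assembly links; candidates reaching the
total (configurable via `min_present`) are flagged top priority. Reports
are sorted by presence count, then correlation, then id, making the
output deterministic and invariant to assembly processing order.

## The synthetic-data generator

`generate_screen_dataset()` emulates the statistical structure the screen
assumes, so that every stage is testable without external transcriptomes:

* **Bait models**: the packaged five-assembly models (relative units, RPM
  and TPM) are the defaults; the bait transcript is present in every
  assembly with expression equal to its model.
* **Planted orthogroup**: one P450-like CDS per assembly, descended from
  a common ancestor by substitutions at `homolog_identity` (default
  0.95), with expression proportional to each assembly's bait model times
  multiplicative log-normal noise `exp(N(0, sigma))`, `sigma = 0.05` by
  default. Codon-aware mutation never introduces premature stops.
* **Decoys**: P450-like peptides (template descendants at 65–90%
  identity, carrying the motifs) and motif-scrubbed random peptides, all
  with expression independent of the bait: log-normal noise around
  tissue means drawn uniformly on [0.1, 200], spanning the observed range
  of the packaged models. Decoys are generated independently per
  assembly, so chance co-expressors cannot form cross-assembly links —
  which is exactly why the five-of-five intersection is powerful.

Defaults (5 assemblies × 250 transcripts, 50 decoy P450s) are desk-scale:
generation plus the full screen runs in a few seconds. Features of real
data the generator does *not* emulate: shared orthology of background
genes across species (real decoys have orthologs; only their
*co-expression* in all five lists is rare), assembly fragmentation and
chimeras, indels between orthologs, count-based measurement noise, and
more than three tissues. Passing tests therefore demonstrate the
machinery and its decision rules, not field performance on real
transcriptomes — the screen's real-data yields (hundreds of P450s,
thousands of co-expressors) are not reproducible here and are not
targets.

Two calibration facts, both computed by the test suite: under the null
(no planted orthogroup) the screen returns zero top-priority candidates
in ≥ 95% of seeds; and with the planted orthogroup at `sigma = 0.05` the
screen recovers exactly the planted candidate in about 95% of seeds — the
binding constraint is the three-tissue p criterion ($r \ge 0.9969$),
which 5% multiplicative noise occasionally breaks in one assembly. At
`sigma = 0.02` recovery is complete across seeds. The packaged scenario
defaults (including `seed = 1`) are fixed, so the shipped checks are
deterministic.

## Kinetics

Velocity follows the standard uncompetitive substrate-inhibition law

$$v = \frac{k_{cat}\,[E]\,S}{K_m + S + S^2/K_i},$$

reducing to Michaelis–Menten as $K_i \to \infty$; the maximum sits at
$S^* = \sqrt{K_m K_i}$. Units: $K_m, K_i, S$ in µM, $k_{cat}$ in 1/min,
$[E]$ in nM, hence $v$ in nM/min and catalytic efficiency $k_{cat}/K_m$
in 1/(µM·min). The source analysis reported substrate inhibition without
printing its model equation; the uncompetitive form is the field's
default and is stated here prominently rather than assumed silently.

Fitting is damped (Levenberg–Marquardt) least squares via
`minpack.lm::nlsLM` with relative tolerances 1e-10 and at most 500
iterations, positivity-bounded parameters, and starting values robust on
inhibition-shaped curves: $K_m$ from the concentration at half-maximal
observed velocity, $k_{cat}$ from $\max(v)/[E]$, $K_i$ at ten times the
largest tested concentration. Standard errors are asymptotic (from the
Jacobian at the optimum); whether published ± values are SEs or SDs is
unstated, so asymptotic SEs are reported and labelled. With
`model = "auto"`, $K_i$ is reported only when the substrate-inhibition
fit reduces the residual sum of squares by ≥ 5% relative to
Michaelis–Menten — the rule that yields "no substrate inhibition
observed" for substrates that genuinely lack it. On Michaelis–Menten
truth the unconstrained $K_i$ estimate diverges and its Jacobian column
vanishes; the resulting singular-Jacobian error is caught and resolved in
favour of the Michaelis–Menten model.

The default simulated assay (`kinetic_scenario()`) uses the preferred
substrate's parameters — $K_m = 1.13$ µM, $k_{cat} = 15.0$/min,
$K_i = 64.3$ µM, enzyme 2.5 nM — with 12 substrate concentrations
log-spaced over 0.25–200 µM in triplicate and 5% multiplicative Gaussian
noise (clipped at zero). The acceptance computation refits 100 such
datasets and reports median estimates; 100 keeps the medians stable to a
few percent while the whole computation stays under a minute.

Mass bookkeeping: oxidative *C-C* phenol coupling removes two hydrogens,
so the product precursor ion is monitored 2 m/z below the substrate
precursor (274.30 → 272.30; 260.00 → 258.00). The packaged MRM table
records the *monitored* settings; for the 288.30 precursors the monitored
product setting (286.20) sits 0.1 below the rule's output (286.30) — the
rule is not forced to match, and `coupled_product_mz(288.30)` returns
286.30. Molar ratios convert mg/g tissue contents through molecular
masses (301.34 g/mol haemanthamine, 287.35 g/mol galanthamine); the
worked example reproduces the ~8.6-fold bulb ratio from contents printed
to three significant figures.

## Assembly statistics and numerical conventions

* **N50**: lengths sorted descending; the sequence whose cumulative sum
  first reaches half the total defines N50 (the standard assembler
  convention; duplication-invariant, order-invariant). Median of an
  even-count set is the mean of the central pair. All residues count
  toward lengths, including N.
* **TPM**: counts are divided by transcript length and rescaled to sum to
  1e6; scale-invariant in the counts, columns validated to 0.1% when a
  matrix is tagged TPM.
* **Coordinates**: 0-based half-open throughout (alignment spans, motif
  positions); the field's 1-based residue numbering is a presentation
  concern.
* **Ties**: homolog search breaks ties by higher raw score then
  lexicographic subject id; ORF search by frame order (+1, +2, +3, −1,
  −2, −3) then leftmost start. Both make results independent of input
  order.
* **Degenerate inputs**: constant or all-zero expression vectors are
  non-matches with a named reason rather than errors; all-zero count
  columns normalize to zero with a warning; empty sequence sets are
  errors for statistics and empty results for searches.

## Known limitations

Alignment statistics are uncorrected Karlin–Altschul; the ORF predictor
ignores non-ATG starts and frameshifts; the generator plants exactly one
orthogroup and mutates without indels; three-tissue correlation p-values
carry a single degree of freedom and should be read as the screen's
historical decision rule, not as a calibrated error rate. The YAML
configuration front end covers scenarios and criteria; orchestration is
deliberately function-level (`run_screen()`) rather than a shell tool.
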