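---
title: "The drivesim inheritance model: simulation and estimation of homing gene drive performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The drivesim inheritance model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivesim)
```

## The biology being modeled

A CRISPR homing gene drive is a genetic element that, in the germline of a
drive/wild-type heterozygote, cuts the homologous wild-type allele and copies
itself into the break by homology-directed repair. Successful copying
("drive conversion") biases transmission above the Mendelian 1/2; failed
copying, where the cut is repaired by end-joining, creates *resistance
alleles* that can no longer be cut. Resistance alleles that preserve the
function of the target gene are called r1; those that disrupt it, r2.
Resistance alleles also form in the *early embryo* when the mother loads the
egg with Cas9 protein and gRNA ("maternal deposition"), cutting target
alleles before the zygotic genome takes over.

`drivesim` models three laboratory architectures in *Drosophila
melanogaster*:

* **standard drive** — one element carrying Cas9, the gRNA and a dsRed
  marker, inserted into the target gene it disrupts;
* **split drive** — the driving element (gRNA + dsRed, targeting the
  X-linked *yellow* gene) lacks Cas9 and depends on an unlinked, EGFP-marked
  Cas9 element on chromosome 2R;
* **synthetic target site drive** — the drive homes into an engineered EGFP
  gene absent from wild populations (autosomal sites B and E, and an
  X-linked site Y).

Both safeguarding architectures confine the drive to laboratory lines while
keeping its mechanics measurable, which is why the package's estimators and
cross catalog are organised around them.

## State space

Each fly is a `locus_genotype`: a sex, one or two target-locus alleles from
{WILD, DRIVE, R1, R2} (one for males at X-linked targets — they are
hemizygous), two autosomal support-locus alleles from {CAS9, ABSENT}, and a
per-target-allele embryo flag from {intact, mosaic_cut, full_cut}. A
`full_cut` flag marks an allele converted to resistance in the embryo; a
`mosaic_cut` flag marks an allele cut in part of the soma only — the fly
shows a mosaic phenotype but the allele is still WILD in its germline, and
can be converted there in the next generation.

The genotype-to-phenotype map (`phenotype_of`) is deterministic: dsRed
travels with the drive allele with perfect penetrance (the two fluorophores
are scored as fully distinguishable); eye EGFP reports the synthetic target
state for synthetic-target drives and Cas9-element carriage for the split
drive; and the recessive body-colour channel is `yellow` exactly when zero
functional (WILD or r1) target alleles remain. Mosaic classes are emitted
post-classification — the microscope rule that a drive-carrying fly counts
as mosaic only below 50% EGFP eye coverage is assumed already applied, so
the simulator emits the final category directly.

## The inheritance model

Events are ordered: **germline modification at gametogenesis → uniform
transmission → fertilisation → early-embryo modification → phenotype**.
This matches the causal order in which the underlying molecular events can
occur and makes every estimator below well defined.

**Germline (per gamete).** In a DRIVE/WILD heterozygote with an active
germline nuclease, the WILD allele becomes DRIVE with probability $c$
(sex-specific: `c_f`, `c_m`), a resistance allele with probability $r$
(r1 with probability `r1_fraction`, else r2), and stays WILD otherwise; one
of the two resulting alleles is then transmitted with equal probability, so
the drive-transmission probability is $(1+c)/2$ and the r2-transmission
probability is $r(1-q)/2$ with $q$ = `r1_fraction`. Any genotype that is
not a DRIVE/WILD heterozygote segregates Mendelian: drive and resistance
homologs have destroyed target sites and are never cut again. The germline
stages (pre-gonial vs. meiotic cutting) are deliberately collapsed into this
single per-gamete outcome distribution, since stage-resolved rates are not
experimentally identified; `c` is parameterised directly as a conversion
probability, not as cut-rate × HDR-fraction.

**Nuclease availability.** The germline needs a genomic gRNA source (the
drive allele itself) plus Cas9 from one of two routes:

1. *genomic* — a CAS9 support allele, or the drive allele itself when the
   architecture carries Cas9; uses (`c_f`/`c_m`, `r_f`/`r_m`);
2. *carryover* — no genomic Cas9, but the individual received maternally
   deposited Cas9 as an egg. Carryover is modeled as all-or-nothing per
   individual: with probability `p_active` the germline runs at
   (`c_carry`, `r_carry`), otherwise at zero. The two-level form reproduces
   the observed per-fly pattern (most exposed flies converting at a common
   rate, an occasional fly not at all), which a single per-allele rate
   cannot.

**Early embryo.** If and only if the mother deposited *both* Cas9 and gRNA
(derived from her own genotype: gRNA iff she carries a drive allele, Cas9
iff she carries a genomic Cas9 source), each WILD allele of the zygote is
independently converted to resistance with probability `e_cut`
(flag `full_cut`), or mosaically cut with probability `e_mosaic` (flag
`mosaic_cut`, state unchanged). Deposition memory is strictly one
generation: a Cas9-less mother who herself received deposited Cas9 can
convert in her *germline* via carryover, but deposits nothing into her own
eggs. Embryo cutting never produces drive alleles — there is no
homology template at that stage.

## Parameters

| parameter | meaning | default | source of default |
|---|---|---|---|
| `c_f`, `c_m` | germline conversion probability (female, male) | 0.74, 0 | split-drive female measurement; X-linked males hemizygous |
| `r_f`, `r_m` | germline resistance probability | 0 | not separately quantified outside the carryover cross |
| `r1_fraction` | share of new resistance alleles that are r1 | 0 | observed qualitatively, never rate-quantified |
| `e_cut` | embryo full-cut probability per WILD allele | 0.74 | split-drive embryo r2 rate |
| `e_mosaic` | embryo mosaic-cut probability | 0 | mosaics observed but not rate-quantified |
| `p_active` | carryover germline active per individual | 15/16 | 15 of 16 exposed flies converted |
| `c_carry`, `r_carry` | conversion/resistance under carried-over Cas9 | 0.54, 0.12 | carryover cross measurements |

All are probabilities; `drive_params()` enforces `c + r <= 1` per sex,
`e_cut + e_mosaic <= 1` and `c_carry + r_carry <= 1`. Defaults are the
split-*yellow* system's measured operating point; analyses of other drives
pass their own values (`table1_params()` collects the published set).

## Cross designs and estimators

`design_catalog()` pins the laboratory crosses: synthetic-target
heterozygote × EGFP-homozygote crosses (both parental sexes where the
target is autosomal), the split-drive scoring cross drive/+; Cas9/+ female
× w1118 male, the two Mendelian controls in which Cas9 and the drive enter
from different parents, the Cas9-carryover crosses, and the
standard-drive comparators.

Estimators consume pooled phenotype count tables, mirroring how flies are
tallied at the microscope. Denominator conventions are pinned per design,
because each readout is only informative in part of the progeny:

* `drive_inheritance_rate` — dsRed fraction; all offspring for
  maternal-transmission readouts and autosomal paternal readouts,
  daughters only for X-linked paternal readouts.
* `conversion_efficiency` — $2p - 1$ of the above; unclamped, so
  sub-Mendelian transmission shows as a negative value.
* `embryo_r2_rate_yellow` — full-yellow fraction among dsRed daughters:
  their maternal allele is the drive, so a yellow body pins an embryo-cut
  paternal allele.
* `embryo_r2_rate_egfp` — EGFP-less fraction among dsRed progeny; restricted
  to daughters for X-linked synthetic targets, where drive-carrying sons
  lack EGFP structurally.
* `germline_r2_rate_sons` — twice the full-yellow non-dsRed son fraction:
  sons display single maternal gametes, and non-converted maternal alleles
  enter half of them.

Mosaic animals stay in denominators and out of numerators (their cut
allele retains germline function); mosaic dsRed-negative flies carry an
ambiguous maternal allele and are excluded from embryo-rate numerators by
the same rule. Uncertainty is reported two ways — a binomial SE and a
Wilson 95% interval — because the published "±" convention for these rates
is not stated; neither is claimed to reproduce it numerically. A
leave-one-cross-out jackknife (`jackknife_se`) is available to flag
brood-level overdispersion that the pooled binomial SE would hide.

`fisher_exact_2x2` implements the exact two-sided test by enumerating, at
fixed margins, all tables whose hypergeometric mass does not exceed the
observed table's (ties accepted within relative tolerance 1e-7 — the
sum-of-small-p-values convention; the doubling convention is deliberately
not offered). `mendelian_check` is an exact binomial test of the pooled
dsRed fraction against 1/2 at α = 0.01; it is valid whenever exactly one
parent carries a single drive allele, including a hemizygous father at an
X-linked target, where all daughters and no sons inherit dsRed and the
overall fraction is still Binomial(n, 1/2) under the 1:1 sex ratio.

## What the simulator does and does not emulate

The generator reproduces the structure of the published experiments:
phenotype classes as scored, X-linkage and hemizygosity, deposition gating,
one-generation carryover, per-fly carryover activity, and pooling of many
small broods. It deliberately omits features of real data that the
estimators do not consume: brood-size variation (offspring counts are
fixed per cross, so pooled counts are mildly under-dispersed relative to
real vials), viability and fitness differences between genotypes, scoring
error (fluorescence is taken as perfectly penetrant), sequence-level
diversity among resistance alleles, somatic Cas9 expression beyond the
mosaic category, multi-generation population dynamics, and off-target
cutting. Passing recovery tests therefore demonstrates internal
consistency of model + estimators at realistic scale — not robustness to
those real-world complications.

Two observations are intentionally outside the model: the two fully yellow
females that nonetheless showed drive conversion (no mechanism is
available to fit), and drive conversion in the early embryo (modeled as
impossible; a sensitivity hook would relax this).

## Numerical and design choices

* **RNG.** One master seed; each cross runs in a substream derived from
  (seed, cross index) by a Lehmer-style mix modulo $2^{31}-1$, so pooled
  experiments are reproducible under any execution order. All uniform
  vectors are drawn unconditionally, keeping the RNG call pattern
  independent of parameter values; this makes common-random-number
  comparisons across parameter grids (e.g. the monotonicity check of dsRed
  fraction in `c_f`) exact couplings.
* **Scale.** The default experiment is 40 crosses × 100 offspring — chosen
  so binomial SEs match the order of the published uncertainties — and
  recovery runs use 50 replicates (16 females for the carryover design,
  matching the experiment). Recovery tolerance is 3 empirical SEs of the
  replicate mean rather than a fixed percentage, so the criterion stays
  calibrated if replicate counts are changed.
* **Degenerate inputs.** Zero-denominator estimates raise errors rather
  than returning NaN; the all-zero contingency table returns p = 1 with a
  warning; empty count tables are valid (header-only TSV) and sum to zero.
* **Ties and bounds.** Wilson intervals are clipped to [0, 1];
  efficiencies on the $2p-1$ scale are never clipped. Fisher tie
  comparison uses relative tolerance 1e-7, matching common practice for
  enumeration-based implementations.
* **TSV dialect.** Count tables are written in a canonical row order with
  lower-case categorical labels and `# key: value` metadata lines, making
  write→read round trips exact and same-seed outputs byte-identical.

## Known limitations

Estimator SEs treat pooled offspring as i.i.d.; with per-cross parental
redraws (carryover activity) the pooled estimator remains unbiased, but its
binomial SE understates the variance contributed by the per-fly activity
mixture — the jackknife SE is the honest uncertainty there. The model's
`r1_fraction` is a free parameter with no measured default, so any analysis
of r1-dependent quantities is a sensitivity exercise. Finally, the
Mendelian check's 0.5 null relies on the fixed 1:1 sex ratio; real
sex-ratio distortion would require conditioning on sex.
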