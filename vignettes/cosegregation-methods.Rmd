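---
title: "Methods: pedigree-aware co-segregation filtering of rare exome variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree-aware co-segregation filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosegr)
```

## The problem

In an extended family where a trait (here, the motivating case is
developmental dyslexia) segregates in a pattern consistent with autosomal
dominance, exome sequencing of a handful of affected and unaffected members
yields tens of thousands of variant calls per person. The discovery question
is combinatorial rather than statistical: which variants are *carried by
every affected sequenced member and by no unaffected sequenced member*, are
rare enough to plausibly be causal, are protein-altering, lie in genes
expressed in the relevant tissue, and — after re-genotyping by an orthogonal
assay (Sanger) across the wider family — still co-segregate with the trait?

`cosegr` implements that filter cascade as a deterministic, traceable
pipeline, together with a gene-dropping simulator that generates data with
exactly the statistical structure the analysis assumes, so every stage is
testable without access to any restricted raw data.

## The model and its assumptions

The inheritance model is autosomal dominant with high or complete
penetrance and a non-zero phenocopy rate:

* a single heterozygous causal allele, introduced by one founder, is
  transmitted through meioses with probability 1/2 per offspring;
* carriers are affected with probability `penetrance` (default 1);
* non-carriers are affected with probability `phenocopy_rate` (default
  0.075, the middle of the 5–10 % population prevalence range for the
  motivating trait) — this is why an affected member whose connection to
  the family line is unclear cannot anchor a transmission argument;
* unaffected status is informative: under complete penetrance an unaffected
  carrier is disqualifying. "High penetrance" is operationalized as
  `max_unaffected_carriers` (default 0), a tolerated count of unaffected
  *typed* carriers, because each published exclusion treats a single
  unaffected carrier as decisive.

Individuals with *uncertain* or *untested* phenotype impose no constraint
anywhere, but the two states are kept distinct (PED phenotype code 9 vs 0)
because reports must distinguish "tested, inconclusive" from "never
tested".

## Stages and the parameters that matter

1. **Ingestion** (`read_variant_calls`). Per-sample discovery VCFs (or one
   multi-sample VCF); multi-allelic records are split into biallelic
   records. The *no-call policy*: per-sample callers emit no reference
   blocks, so a variant absent from a sample's VCF is `hom_ref` for that
   sample, while an explicit `./.` is missing and unconstrained.
2. **MNV merging** (`merge_adjacent_substitutions`). Callers may emit a
   two-base substitution (delins) as two adjacent SNV rows. Runs of
   single-base substitutions at consecutive positions with *identical
   per-sample genotype vectors* — the only phase evidence available without
   reads — merge into one multi-base record; the merged record's per-sample
   read support is the minimum over constituents (weakest evidence), and
   provenance is kept in a `MERGED` note. The operation is idempotent and
   never touches indels or positions shared by several records.
3. **Read support** (`support_filter`, `min_alt_reads = 20`). Non-reference
   exome calls with fewer than 20 reads carrying the alternative allele are
   downgraded to missing, not deleted: weak evidence is treated as absence
   of evidence. The published rule does not state whether support was
   required per call or per variant, so `support_mode` offers `"per_call"`
   (default, stricter) and `"any_sample"`.
4. **Shared-candidate scan** (`shared_candidates`). Exactly the variants
   with a carrier genotype (default `{het}`; homozygous carriers are
   optionally allowed) in *every* affected sequenced member and `hom_ref`
   in *every* unaffected sequenced member. Exception individuals (see
   below) are still required to carry the variant here.
5. **Annotation cascade** (`filter_cohort_db`, `filter_population_maf`,
   `filter_expression`, `filter_consequence`). Set-intersection semantics:
   each filter is idempotent and order-independent; order affects only
   which reason code a doubly-failing variant gets. Cohort-database removal
   is presence-based (any variant seen in the in-house exome database is an
   artifact or too common locally), population MAF is a strict `< 1 %`
   rule with absent frequencies treated as novel, expression is a binary
   per-gene whitelist flag (whether the original analysis used a binary
   call or an expression-level threshold is unstated; binary was chosen as
   the only reproducible reading), and consequence keeps
   `non_synonymous` by default.
6. **Validation override** (`apply_validation`). Sanger-style genotypes
   replace exome calls for the same (variant, individual) and may type
   relatives never exome-sequenced. Overrides carry provenance and are
   exempt from the read-support rule.
7. **Co-segregation verdicts** (`cosegregation_test`). Evaluated over all
   typed individuals, in a fixed order: `FAIL_MONOMORPHIC` (no typed
   carrier — the validation-refuted artifact class), then
   `FAIL_MISSING_IN_AFFECTED`, then `FAIL_UNAFFECTED_CARRIER`, then the
   exception-transmission check, else `PASS_COSEGREGATING`.

### Exception individuals and transmission confirmation

An affected member one of whose parents is untyped with unknown phenotype
(the worked example's IV:9, whose mother has uncertain status and whose
father is unaffected) is a modelling dilemma: given a population phenocopy
rate, the member might be affected without the family's causal allele. The
package's reading, which reproduces every published narrative: at the scan
stage the exception individual must still carry the variant (the published
shared set explicitly included the exception member), and the exception
only defers the *transmission* question to the verdict stage.

`confirm_transmission` searches genealogical lineages — up through parents,
then optionally down to a relative; a lineage must leave the individual via
a parent, because carriers among the individual's own descendants say
nothing about where the allele came from. A lineage is *contradicted* if a
typed non-carrier sits on it. Outcomes:

* **confirmed** — some lineage to another typed carrier has carriers at
  every typed step;
* **unconfirmed** — other typed carriers exist but every lineage to them is
  contradicted (the pattern that excluded the second candidate gene:
  typed non-carrier mother plus unaffected non-carrier father) →
  `FAIL_ANCESTRY_UNCONFIRMED`;
* **indeterminate** — no other typed carrier is reachable. Indeterminate
  does **not** fail the variant: the published analysis retained its
  final candidate despite untyped branches. The PASS verdict carries a
  caveat note instead.

This lineage rule is the most literal reading of the published exclusion
narrative and is flagged as interpretive: the source does not define
"common ancestor" confirmation precisely.

## The simulator: a stated world

`simulate_dataset` generates the world the analysis assumes:

* the default pedigree is the packaged worked-example family (ten
  sequenced members, seven affected);
* one founder introduces the causal heterozygous variant; transmission is
  Mendelian (`gene_drop`); phenotypes follow penetrance/phenocopy
  (`assign_phenotypes`);
* **ascertainment conditioning**: transmission and phenotypes are redrawn
  until at least `min_affected_sequenced` (default 2) sequenced members are
  affected — a family study exists only because the trait visibly
  segregates; without this, a fraction of replicates would describe
  families nobody would have ascertained (and the scan would be undefined);
* the background is a common pool (MAF ~ U(0.05, 0.5), founder genotypes in
  Hardy–Weinberg proportions, dropped through the pedigree per variant,
  with no linkage disequilibrium — a stated non-goal) plus founder-private
  rare variants (mean 700 per founder, half of them "novel" with no
  population frequency);
* **per-sample counts**: the published per-sample call counts have mean
  50,556 and SD 6,524 — a 13 % coefficient of variation that binomial
  sampling cannot produce. The generator models a per-sample *callable
  fraction*: each sample's target count is drawn from N(mean, SD)
  (truncated at ±3 SD) and that sample's background non-reference calls
  are thinned to the target. The pool is oversized by `1/callable_margin`
  (default 0.70) so targets up to +3 SD stay attainable. The causal
  variant is never thinned: the causal locus is modelled as well covered
  in every sample, consistent with the published ≥ 20-read support for
  every validated variant;
* depths are Poisson(150) with Binomial(depth, 1/2) alternative reads for
  heterozygotes; spurious calls get Poisson(12) alternative reads, so the
  read-support threshold has genuine work to do;
* errors (`inject_errors`): false negatives drop true het calls to
  missing; false positives add spurious het calls; `n_universal_fp`
  injects artifact variants called het in *every affected* sample with
  strong support — the error class that survives every desk filter and is
  unmasked only by validation (monomorphic), mirroring the published
  artifact candidate;
* validation genotypes are simulation truth (`validation_error_free`) for
  the causal and artifact loci across all family members — the Sanger
  follow-up of candidate loci.

What the generator does **not** emulate: linkage disequilibrium and shared
haplotype blocks (so the simulated shared-candidate set is smaller than the
published 283 — most of that set plausibly reflects haplotype sharing and
recurrent platform artifacts), sequence context, indels, batch structure
(the published two-batch sequencing design is reproducible by running the
scan twice with different subsets, but is not a dedicated mode), and
genotyping error in the validation assay. A green recovery test therefore
establishes the pipeline's correctness *given the inheritance model*, not
the field sensitivity of the original assay.

## Numerical and design choices

* **Determinism**: one master seed; replicate seeds are `seed + rep`
  (kept below 2^31); identical configs give byte-identical files. Report
  files exclude timestamps; logs/metadata may carry them.
* **Boundary conventions**: MAF filter removes `>= threshold` (strictly
  below survives, so a 1 % variant is removed); support filter keeps
  `>= min_alt_reads`; calls with unknown read support are kept (cannot be
  assessed).
* **Config format**: JSON rather than YAML — no YAML parser is available in
  the supported dependency set, and the schema is unchanged.
* **Tie-breaks**: variants sort by (chrom, pos, ref, alt) with chromosome
  names compared lexically; all outputs inherit that order.
* **Degenerate inputs**: empty validation tables and empty PASS sets are
  valid (a header-only VCF is still written); a pedigree subset with no
  affected sequenced member makes the scan undefined and is an error, not
  an empty result.
* **Reduced-scale acceptance runs**: the 50-replicate recovery experiment
  runs with background mean 4,000 (not 50,556) to stay inside runtime
  budgets; recovery of the implanted variant depends on the inheritance and
  error model, not on background size. The full-scale background is
  exercised once for the count-calibration check.
* **No multiple-testing correction**: the cascade is a deterministic
  filter, not hypothesis testing; no p-values are produced anywhere.

## Worked example

```{r example}
fx <- make_fig1a_fixture()
res <- run_pipeline_core(fx$table, fx$ped, fx$annotations,
                         validation = fx$validation, whitelist = fx$whitelist,
                         scan = fx$scan, model = fx$model)
res$trace$stages
res$pass_keys
```

Six exome records (the two-base causal variant arrives as two adjacent
SNVs) merge to five candidates; all five survive the scan and desk
filters; validation excludes four — one monomorphic artifact, one
transmission-unconfirmed, two with unaffected carriers — leaving the single
co-segregating delins.

## Known limitations

* The packaged pedigree encodes only the published subtree; the full
  62-member structure exists only as a drawing and the invented connecting
  individuals are a documented synthetic reconstruction.
* The lineage rule for transmission confirmation is an interpretation (see
  above); alternative readings (e.g. requiring typed carriers on both
  sides of a common ancestor) would be stricter.
* Genotype vectors are the only phasing evidence for MNV merging; true
  in-cis adjacent variants in different samples' haplotypes would merge
  incorrectly, and read-backed phasing is out of scope.
* The simulator's cohort database is a per-variant Bernoulli flag, not 700
  simulated exomes; frequency-within-database filtering is therefore
  config-exposed but untested against a generative model.
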