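# cosegr

Pedigree-aware co-segregation filtering of rare exome variants for
autosomal-dominant traits.

## What problem this solves, and for whom

Family studies of dominant traits sequence a handful of affected and
unaffected relatives and then ask a combinatorial question: among the
~50,000 variant calls per exome, which are carried by **every affected**
sequenced member and by **no unaffected** sequenced member, are rare,
protein-altering, expressed in the relevant tissue, and — after orthogonal
re-genotyping (Sanger) across the wider family — still co-segregate with
the trait? `cosegr` is for genetic epidemiologists and rare-disease
bioinformaticians who need that filter cascade as a reproducible, traceable
pipeline rather than a pile of ad-hoc scripts.

## The procedure

For variant *v* with carrier genotype set *C* (default {het}), affected
sequenced set *A*, unaffected sequenced set *U*:

```
shared(v)  <=>  (forall a in A: g(a,v) in C)  and  (forall u in U: g(u,v) = 0/0)
```

under a no-call policy where a variant absent from a per-sample VCF is 0/0
and an explicit `./.` is unconstrained, with non-reference calls requiring
≥ 20 reads carrying the alternative allele, and adjacent single-base
substitutions with identical genotype vectors merged into one
multi-nucleotide (delins) record. Shared candidates then pass rarity
(absent from an in-house cohort database; population MAF < 1%),
consequence (non-synonymous), and brain-expression filters. Validation
genotypes override exome calls, and each surviving variant receives a
verdict under a dominant model with tolerated unaffected-carrier count *k*
(default 0, complete penetrance among typed individuals):
`FAIL_MONOMORPHIC`, `FAIL_MISSING_IN_AFFECTED`, `FAIL_UNAFFECTED_CARRIER`,
`FAIL_ANCESTRY_UNCONFIRMED` (an exception individual whose every lineage
to another typed carrier is contradicted by a typed non-carrier), or
`PASS_COSEGREGATING`.

A gene-dropping simulator (Mendelian transmission from a founder,
penetrance / phenocopy phenotype model, per-sample callable-fraction
calibration to mean 50,556 / SD 6,524 calls, cohort-database and
genotyping-error models) generates complete synthetic datasets so the whole
pipeline is testable offline. See `vignettes/cosegregation-methods.Rmd`
for the model, parameter meanings and design rationale.

## Worked example

The packaged fixture encodes the published worked example: ten sequenced
family members (seven affected), five candidate variants whose exome calls
all survive the shared scan, and validation genotypes that exclude four of
them.

```r
library(cosegr)
fx <- make_fig1a_fixture()
res <- run_pipeline_core(fx$table, fx$ped, fx$annotations,
                         validation = fx$validation, whitelist = fx$whitelist,
                         scan = fx$scan, model = fx$model)
print(res)
#> <filter_trace>
#>                               stage n_in n_out
#>                              ingest    6     6
#>                           merge_mnv    6     5
#>  support_filter[0 calls downgraded]    5     5
#>                         shared_scan    5     5
#>                           cohort_db    5     5
#>                      population_maf    5     5
#>                          expression    5     5
#>                         consequence    5     5
#>                       cosegregation    5     1
#> PASS_COSEGREGATING: 1 variant(s) [3:134264558:GA:TT]
```

Six exome records (the causal two-base delins arrives as two adjacent
SNVs) merge to five candidates; validation excludes four — the monomorphic
artifact (GET4), two variants carried by unaffected members (ZNF507,
RNF152), and one whose transmission from a common ancestor could not be
confirmed:

```r
print(res$verdicts[["11:61560000:C:T"]])
#> <11:61560000:C:T: FAIL_ANCESTRY_UNCONFIRMED [IV:9]>
#>   transmission of the variant to IV:9 from a common ancestor was not confirmed
```

The single passing key `3:134264558:GA:TT` is the heterozygous GA→TT
delins carried by all seven affected members and no typed unaffected
member.

The same run works from files:

```sh
Rscript -e 'cosegr::write_fig1a_fixture("fx")'
Rscript -e 'cosegr::run_pipeline("fx/fig1a_config.json")'   # writes fx/out/
```

or through the CLI (installed under `exec/`):

```sh
cosegr fixture  --out fx
cosegr run      --config fx/fig1a_config.json
cosegr simulate --seed 1 --out simdata          # full synthetic dataset
cosegr recover  --seed 1 --reps 20 --out rec.tsv
```

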