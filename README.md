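# chemotypeR

Chemotype prediction for grass-endophyte strains from PCR presence/absence
profiles of alkaloid-biosynthesis genes.

*Epichloë* fungal endophytes live symbiotically inside cool-season grasses
and synthesize four classes of alkaloids: ergot alkaloids (EAS gene
cluster), indole–diterpenes (IDT/LTM cluster), lolines (LOL cluster) and
peramine (the multi-domain `ppzA` gene, formerly `perA`). Peramine and
lolines deter insects and are safe for grazing livestock; ergot alkaloids
and indole–diterpenes poison livestock. Screening strains for
**animal-safe** chemotypes — strains whose genomes cannot encode any toxic
alkaloid — is the gating step for using endophytes in forage-grass
breeding. Conventional PCR on the pathway genes gives a cheap
presence/absence profile per strain; this package turns such profiles into
predicted chemotypes.

## The inference

Each pathway is a declarative dependency model: a DAG of metabolites in
which a production step for metabolite *m* is gated by an all-of set of
genes *G(m)* and an optional precursor *p(m)*. A metabolite is
**producible** iff

```
producible(m)  <=>  (forall g in G(m): present(g))  and
                    (p(m) is none or producible(p(m)))
```

evaluated in topological order (an independent fixed-point oracle is
bundled and cross-checked in the tests). The bundled default models encode:

* **PPZ** — peramine (PER) needs the seven `ppzA` segments
  A1,T1,C,A2,M,T2 plus the reductase domain R (allele *ppzA-1*); the
  mutually exclusive ΔR allele (*ppzA-2*) lacks the final release step and
  yields pyrrolopyrazine-1,4-diones instead.
* **EAS** — chanoclavine I (CC) ← {dmaW, easF, easC, easE}; D-lysergic acid
  (D-LC) ← CC + {easD, easA, easG, cloA}; ergovaline (ERV) ← D-LC +
  {lpsA, lpsB, easH}; ergonovine (EN) ← D-LC + lpsC; lysergic acid
  α-hydroxyacetamide (LAH) ← EN + {easO, easP}.
* **IDT** — paspaline (PAS) ← {idtG, idtB, idtM, idtC, idtS}; paxilline
  (PAX) ← PAS + {idtP, idtQ}; terpendole K (TDK) ← PAX + {idtF, idtK};
  lolitrem B (LTM-B) ← TDK + {idtE, idtJ}.
* **LOL** — the first committed intermediate AcAP needs all five of
  {lolC, lolF, lolD, lolT, lolU}; N-formyl-/N-acetylloline need AcAP plus
  the remaining six cluster genes.

On top of producibility the package calls the mating type (mtAC/mtBA
idiomorphs), the `ppzA` allele, per-cluster pattern codes, a chemotype
type (1–4: peramine only; peramine + ergot + indole–diterpenes; ergot +
paspaline only; ergot + indole–diterpenes without peramine) and a
livestock-safety category (I = no toxic product producible, II
otherwise). A survey module recomputes infection frequencies
(100·infected/sampled, half-up at 2 decimals) and roll-ups, and a seeded
simulator generates profiles with ground-truth chemotypes for end-to-end
validation.

## Worked example

The package bundles the marker table of a 20-strain *E. bromicola* survey
from *Elymus* grasses of Northwest China:

```r
library(chemotypeR)
profiles <- read_profiles(chemotype_example("elymus_profiles.tsv"))
results  <- run_pipeline(profiles)
results
#> chemotype_results: 20 strain(s)
#>   types:       1=4 2=6 3=5 4=5 unclassified=0
#>   categories:  I=4 II=16
#>   mating:      A=20 B=0 undetermined=0 conflict=0

head(as.data.frame(results)[, c("strain", "ppz_allele", "producible",
                                "chem_type", "safety_category")], 3)
#>   strain ppz_allele                  producible chem_type safety_category
#> 1   ADX8     ppzA-1 PER,CC,D-LC,ERV,PAS,PAX,TDK         2              II
#> 2  ADX12     ppzA-1 PER,CC,D-LC,ERV,PAS,PAX,TDK         2              II
#> 3   ADX9     ppzA-1 PER,CC,D-LC,ERV,PAS,PAX,TDK         2              II
```

Four strains (LE1, LE3, LE6, LE7) carry the full-length `ppzA` but no EAS
or IDT genes: they can only make peramine, land in type 1 / category I,
and are the animal-safe candidates. The 16 remaining strains carry the
11-gene EAS core but lack the terminal `lpsC`/`easO`/`easP`, so their
ergot set stops at {CC, D-LC, ERV}; 11 of them additionally reach
{PAS, PAX, TDK} (no strain can make lolitrem B, since `idtE`/`idtJ` are
universally absent).

The survey side:

```r
summary <- aggregate_survey(read_survey(chemotype_example("elymus_survey.tsv")))
summary$total_samples   # 109
summary$total_strains   # 20
summary$records$frequency
#> [1] 28.57 57.14 81.82 16.67  8.33 66.67
```

A command-line driver wraps the same functions
(`predict`, `survey`, `simulate`, `validate-model`):

```sh
Rscript inst/exec/chemotype predict \
  --profiles inst/extdata/elymus_profiles.tsv --out out/
```

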