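# dsindex

Multivariate **disease severity index** for preclinical Alzheimer's disease
(AD) research, from regional brain morphometry.

Subjective memory decline (SMD) — self-reported memory worsening with
objectively normal test scores — is heterogeneous: some of it is the
earliest sign of AD, much of it is not. `dsindex` implements a way to pick
out the at-risk subgroup from structural MRI alone:

1. **Train** an OPLS (orthogonal projections to latent structures)
   discriminant model separating AD patients from healthy controls (HC)
   using a table of regional morphometry (by default 187 measures: 68
   Desikan-Killiany cortical thicknesses, 68 cortical volumes, 51
   subcortical volumes), with intracranial volume (ICV) as a nuisance
   covariate and stratified 7-fold cross-validation.
2. **Project** unseen subjects (e.g. the SMD group) onto the model to get a
   per-subject *severity index* on the coded-response scale: close to 0 =
   control-like atrophy pattern, close to 1 = AD-like pattern.
3. **Subtype** at the 0.5 cutoff (AD-like vs HC-like).
4. **Validate** the subtypes against longitudinal follow-up: progression
   proportions and ratios, Kaplan-Meier curves, log-rank tests,
   Benjamini-Hochberg multiplicity correction, MMSE (>= 24) and amyloid
   SUVR (>= 1.5) threshold rules.

A seeded synthetic-cohort generator with a planted AD atrophy pattern
(hippocampus, entorhinal, inferior parietal, amygdala, precuneus down;
inferior lateral ventricles up) makes the whole pipeline testable without
clinical data access.

## The model

With X the (ICV-adjusted, column-standardized) subject x feature matrix and
y the centred class code (HC = 0, AD = 1), each orthogonal component is
extracted as

    w* ∝ Xᵀy,  t* = Xw*,  p* = Xᵀt*/(t*ᵀt*)
    w_o ∝ p* − (w*ᵀp*)w*,  t_o = Xw_o,  p_o = Xᵀt_o/(t_oᵀt_o)
    X ← X − t_o p_oᵀ

and the single predictive component on the deflated matrix is

    w ∝ Xᵀy,  t = Xw,  p = Xᵀt/(tᵀt),  c = yᵀt/(tᵀt)

The severity index of a subject x is `c·t(x) + ȳ` after removing the stored
orthogonal variation from x. Model quality is the cross-validated
`Q²(Y) = 1 − PRESS/SS` (> 0.05 significant, > 0.5 good, by the field's
convention), with sensitivity/specificity of the cross-validated
predictions at 0.5.

## Worked example

```r
library(dsindex)

cfg    <- simulationConfig(seed = 1)   # study-calibrated defaults
cohort <- generateCohort(cfg)
cohort
#> MorphCohort: 238 subjects x 187 ROI features
#> groups: AD=38, HC=69, MCI=45, SMD=86

model <- trainSeverityModel(cohort, disease = "AD", control = "HC", seed = 1)
model
#> OplsModel: 187 features, 1 orthogonal component(s)
#> coding: HC=0, AD=1; intercept 0.355
#> trained on 107 subjects

X    <- featureMatrix(cohort, c("HC", "AD"))
y    <- as.numeric(cohortGroups(cohort)[cohortGroups(cohort) %in% c("HC", "AD")] == "AD")
vols <- roiSchema(cohort)$name[roiSchema(cohort)$kind == "volume"]
crossValidate(X, y, k = 7, nOrth = model@nOrth, seed = 1,
              icvValues = icv(cohort)[rownames(X)], volumeCols = vols)
#> OplsCv: 7-fold, nOrth=1 | Q2 = 0.949, sensitivity = 1.000, specificity = 1.000

idx <- classifySubtypes(computeIndex(model, cohort, "SMD"))
table(idx$subtype)
#> AD-like HC-like
#>      11      75
head(idx, 3)
#>   subject_id       index subtype cutoff
#> 1     SMD001  0.87287710 AD-like    0.5
#> 2     SMD002 -0.07431623 HC-like    0.5
#> 3     SMD003  0.06443163 HC-like    0.5
```

The Q² of 0.949 says 7-fold cross-validated predictions explain ~95% of the
class-code variance — a strongly separable cohort, as the |d| = 2.5 planted
effect intends. The model recovers exactly the 11 synthetic SMD subjects
planted with the AD atrophy pattern (index >= 0.5), e.g. SMD001 at 0.87.

Follow-up validation of the subtypes:

```r
fu     <- generateFollowup(cohort, cfg)
groups <- setNames(cohortGroups(cohort), subjectIds(cohort))
groups[idx$subject_id] <- ifelse(idx$subtype == "AD-like", "AD-like SMD", "HC-like SMD")
counts <- outcomeTable(finalOutcome(fu), groups)
unlist(progressionStats(counts, "AD-like SMD", "HC")[c("percentA", "percentB", "ratio")])
#> percentA percentB    ratio
#>     81.8      8.8      9.3
```

i.e. in this simulated replicate 81.8% of AD-like SMD subjects progressed
to MCI, dementia or death versus 8.8% of healthy controls (9.3x) — the
per-seed realization of the configured outcome frequencies. One call runs
everything (`runPipeline(runConfig(outDir = "run1", seed = 1))`), writing
`cohort.csv`, `model.json`, `index.csv`, `report.json` and a log.

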