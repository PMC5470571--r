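# qmriMorph

Quantitative-MRI brainstem morphometry in R, with a fully synthetic
ground-truth phantom so that every stage of the analysis is testable without
any patient data.

## The scientific problem

Traumatic spinal cord injury triggers remote neurodegeneration in the
brainstem: volume loss in the corticospinal tracts and medial lemniscus, and
myelin loss in structures such as the periaqueductal grey, and the magnitude
of these changes tracks clinical impairment. Detecting such changes from
in-vivo MRI requires a chain of quantitative methods:

1. **Relaxometry.** Multi-echo spoiled gradient-echo (FLASH) acquisitions at
   three weightings (T1w 25 ms/23°, PDw 25 ms/4°, MTw 37 ms/9°; echoes
   2.46–17.22 ms plus 19.68 ms for PDw/T1w) yield quantitative maps of
   magnetisation-transfer saturation (MTsat, myelin-sensitive), the
   longitudinal relaxation rate R1, and the effective transverse relaxation
   rate R2\* (iron-sensitive). The steady-state signal is
   `S = A sinα (1−δ)(1−E1) / (1 − cosα (1−δ) E1) · exp(−TE·R2*)` with
   `E1 = exp(−TR·R1)`; R2\* comes from the log-linear decay of the PDw
   echoes, R1 and A from the dual-flip-angle rational approximation, and the
   MT saturation δ from the MTw signal given A and R1.
2. **Tissue templates.** A multivariate Gaussian mixture over image channels
   with *spatially varying* class priors, fit by Expectation-Maximization
   across spatially aligned subjects, learns population tissue probability
   maps (TPMs) of brainstem compartments.
3. **Morphometry.** Stationary-velocity diffeomorphic registration aligns
   every subject to an evolving population mean; the Jacobian determinants of
   the deformations carry local volume change (tensor-based morphometry,
   det J < 1 = atrophy), and the quantitative maps are warped unsmoothed into
   template space for voxel-based quantification.
4. **Inference.** Voxel-wise general linear models with nuisance covariates
   (age, total intracranial volume, scanner), a cluster-defining threshold of
   p = 0.001, and cluster-level family-wise-error correction at p = 0.05 by
   Gaussian-random-field theory within regions of interest.
5. **Clinical scoring.** ISNCSCI motor/sensory scores (UEMS/LEMS 0–50,
   pinprick/light-touch 0–112), neurological level of injury, AIS
   completeness, and the SCIM functional-independence measure (0–100).

Because real patient MRI for such studies is generally not public, the
package ships a phantom simulator that generates brainstem-like cohorts with
known tissue parameters, smooth bias fields, subject-specific diffeomorphic
deformations, a patient group with localized atrophy plus myelin reduction,
and clinical scores linked to the lesion magnitude. Every estimator in the
chain is validated against this ground truth.

## Worked example

```r
library(qmriMorph)

## clinical layer: the packaged 30-patient cohort table
tab <- readCohortTable(system.file("extdata", "table1_cohort.csv",
                                   package = "qmriMorph"))
summarizeCohort(tab)
#>     measure  n  mean    sd    min   max
#> 1 age_years 30 44.67 16.72 19.080  72.6
#> 2 tsi_years 30  3.02  5.42  0.669  23.8
#> 3      lems 30 15.10 20.49  0.000  50.0
#> 4      uems 30 42.37 11.27 14.000  50.0
#> 5        pp 30 58.00 28.14 13.000 112.0
#> 6        lt 30 68.33 25.99 16.000 112.0
#> 7      scim 29 57.90 25.73 19.000 100.0
```

Mean UEMS 42.4, LEMS 15.1, pinprick 58.0, light touch 68.3 and SCIM 57.9
(over the 29 patients with a recorded SCIM) summarize the neurological and
functional state of the cohort; time since injury is reported in years.

```r
## signal model and a small synthetic subject
p <- defaultProtocols()
spgrSignal(1000, 1.0, 0, 0, p$T1w, TE = 0)
#> [1] 94.3744        # steady-state T1w signal for A=1000, R1=1/s

cfg   <- phantomConfig(grid = c(24L, 32L, 48L), noiseSd = 2)
truth <- makePhantom(cfg, seed = 1)
ech   <- simulateSubject(truth, noiseSd = 2, seed = 2)
qm    <- fitQMaps(ech, brainstemMask(truth))
qm
#> QMaps 24x32x48 (11763 mask voxels)
#>   MTsat 3.12 p.u. | R1 0.95 1/s | R2* 23.0 1/s (mask medians)
```

The recovered mask medians sit on the simulated white-matter values
(MTsat 3 p.u., R1 0.95 1/s, R2\* 24 1/s). `runPipeline()` chains all stages
— simulation, map fitting, EM segmentation, population-template
construction, the group GLM with cluster-level FWE correction, and the
clinical summary — and writes `results_clusters.csv` (columns `modality,
p_fwe, extent_vox, z_peak, x_mm, y_mm, z_mm, roi`) plus per-stage JSON
provenance records.

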