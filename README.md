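# mdtwposture

Template-based recognition of twelve high-knee-flexion occupational
postures from six lower-limb joint-angle time series, using a weighted
multi-dimensional Dynamic Time Warping (mDTW) distance and a
k-nearest-neighbour classifier.

## Who this is for

Researchers in wearable-sensor biomechanics and occupational ergonomics
who have IMU-derived flexion–extension angles for the left and right
ankle, knee and hip (nominally 60 Hz) and want to identify when a wearer
is kneeling (dorsiflexed DK, plantarflexed PK, supported SK), squatting
(flatfoot FS, heels-up HS), sitting (adult chair ACS, child chair CCS,
crossed-leg CLS, side SS), stooping (STP), standing (STD) or walking
(WLK) — postures with knee flexion beyond 120° being the ones implicated
in occupational knee osteoarthritis risk.

## The method

Every trial is a 6 × N matrix of angles (degrees).  Templates and query
sequences are linearly resampled to 101 points and each channel is
min–max normalized to [−1, 1].  Per channel, the dissimilarity between a
template *T* and a sequence *S* is the banded DTW distance: over local
costs *D*(m,n) = |t_m − s_n|, the monotone path from (1,1) to (M,N) with
moves (+1,0), (0,+1), (+1,+1) minimizing the accumulated cost, with the
Sakoe–Chiba constraint |m − n| ≤ 50 (a maximum warping of 49.5% at 101
samples).  The six channel distances are fused linearly,

    D_mDTW = 0.26·D_LAnkle + 0.20·D_RAnkle + 0.72·D_LKnee
           + 1.00·D_RKnee + 0.67·D_LHip + 0.76·D_RHip

(the tuned default; an initial 0.25/0.25/0.75/1.00/0.75/0.75 vector is
also provided), and the query takes the label of its nearest template
(k = 1).  Model selection utilities reproduce the full
algorithm-building protocol: stratified 80/20 holdout, five-fold
cross-validation, and grid searches over the band half-width, k and the
channel weights.  Evaluation utilities compute confusion matrices,
per-class sensitivity/specificity/balanced accuracy, row-percentage
tables and grouped-posture summaries.

Because the original recordings are available on request only, the
package includes a first-class synthetic kinematics generator
(`generate_cohort()`) that emulates the study's trial structure —
stand → descend → 5 s hold → ascend → stand, with lead-in/out steps,
class-specific movement signatures, inter-subject variability and
multi-stride gait — so the whole pipeline is testable end to end.

## Worked example

```r
library(mdtwposture)

cohort <- generate_cohort(n_subjects = 5, trials_per_class = 2,
                          n_novel = 1, master_seed = 42)
res <- classify_batch(cohort$build_queries, cohort$library)
cm  <- confusion_matrix(query_labels(cohort$build_queries), res$predicted)
metrics_report(cm)
#> <metrics_report> overall accuracy 100.0%
#>  class sensitivity specificity balanced_accuracy
#>     DK         100         100               100
#>     ...
#> mean sensitivity 100.0% +/- 0.0, mean specificity 100.0% +/- 0.0

knn_classify(cohort$novel_queries[[5]], cohort$library)
#> <classification> predicted SK (k = 1, band 50)
#> nearest templates:
#>  template_id label combined
#>    SK_S03_02    SK 36.06311
#>    SK_S03_01    SK 36.51891
#>    SK_S01_02    SK 36.82816
#>    FS_S01_01    FS 38.61277
#>    FS_S01_02    FS 38.89071
```

Held-in queries (subjects whose templates are in the library) classify
essentially perfectly under these separable synthetic conditions; novel
participants classify less accurately (their idiosyncratic movement
habits are unrepresented), and multi-stride walking sequences are
systematically *not* recognized from single-stride walking templates —
the method's documented failure mode.  The `combined` column is the
weighted mDTW distance; smaller is more similar.

A command-line interface wraps the same functions:

```sh
inst/exec/mdtwposture simulate --subjects 5 --trials-per-class 2 --seed 1 --out run/
inst/exec/mdtwposture classify --library run/library --input run/trials/trial_0001.csv
inst/exec/mdtwposture tune --library run/library --what band --seed 1
inst/exec/mdtwposture evaluate --predictions preds.csv --grouping default
```

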