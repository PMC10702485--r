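# cinegate

Cine-MRI motion analysis for choosing the gating technique in MR-guided
lung SBRT.

## The problem

On an MR-Linac, lung stereotactic treatments can be delivered in free
breathing (FB) or in repeated deep-inspiration breath-holds (DIBH). DIBH
suppresses target motion but is slower and more demanding for the
patient, so for apical lung lesions — which often barely move — the
choice should rest on a measurement. The delivery system tracks the gross
target volume (GTV) on a sagittal cine-MRI (4 frames/s) and gates the
beam off when more than 5% of the GTV leaves a user-drawn boundary, but
it does not export positional data: only the cine video, with the GTV
contour burned in as a red overlay and the gating boundary in yellow.

cinegate recovers quantitative motion from those overlays and applies a
simple decision rule. Per cine, motion is summarized as the standard
deviation of the GTV centroid position per visible axis
(antero-posterior and cranio-caudal),

$$\mathrm{SD}_{axis} = \sqrt{\tfrac{1}{n-1}\textstyle\sum_k (x_k - \bar x)^2},$$

computed over the valid frames (restricted to the breath-hold plateaus
for DIBH traces). Free-breathing delivery is supported when the
simulation-cine motion satisfies $\mathrm{SD}_{AP} < 2\,\mathrm{mm}$ and
$\mathrm{SD}_{CC} < 2\,\mathrm{mm}$ (strict), in which case the
GTV-to-PTV margin can be reduced from the standard 5 mm to the 3 mm
margin otherwise reserved for breath-hold plans; the package also
aggregates the dosimetric consequences of that margin change and screens
motion against anatomical surrogates at cohort level.

Because patient cine cannot be shipped, the package includes a
ground-truthed synthetic cine generator (respiratory waveform → rendered
overlay frames → PNG stack) with which the entire pipeline — overlay
segmentation, sub-pixel centroid tracking, plateau detection, gating
simulation — is validated.

## Worked example

```r
library(cinegate)

# a free-breathing patient: simulate a 60 s cine, track it, decide
les   <- lesion_spec()                       # 1.0 x 1.5 cm ellipse
truth <- generate_trace(motion_model("FB", amplitude_ap = 0.15,
                                     amplitude_cc = 0.2),
                        duration = 60, frame_rate = 4, seed = 1,
                        rest_center = les$rest_center)
stack <- render_frames(truth, les)
trace <- track_cine(stack)
(s <- motion_sd(trace))
#> <motion_summary> SD AP 0.108 cm, CC 0.153 cm (whole_cine, n = 240, 0 invalid)
recommend_gating(s)
#> <gating_recommendation> FB (GTV-to-PTV margin 0.3 cm)
#>   ap: SD 0.108 cm < 0.200 cm
#>   cc: SD 0.153 cm < 0.200 cm
gate_cine(stack)
#> <gating_result> 240 frames, duty cycle 100.0% (threshold 5%)
```

The tracked SDs (0.108 / 0.153 cm) recover the generated sinusoid
amplitudes (0.15 / 0.2 cm) through the $A/\sqrt2$ law despite the 0.35 cm
pixels; both axes are below the 2 mm threshold, so free breathing with
the narrow margin is supported, and the gating simulation confirms the
beam would stay on throughout.

Cohort-level operations run on the bundled per-patient tables:

```r
correlation_screen(read_patient_table())
#>                            pair          r r_rounded n
#> 1          cc_motion~gtv_volume -0.2539993     -0.25 6
#> 2      cc_motion~gtv_lung_ratio -0.2368525     -0.24 6
#> 3 cc_motion~hepatic_dome_motion -0.1786543     -0.18 6

agg <- dvh_aggregate(read_dvh_table())
agg[agg$index == "Dmax", c("structure", "index", "mean_diff_rounded")]
#>                 structure index mean_diff_rounded
#> 9      contralateral_lung  Dmax             -1.73
#> 12             chest_wall  Dmax             -2.55
#> 13 trachea_bronchial_tree  Dmax             -3.00
```

All three correlations are weak — no pre-treatment anatomical surrogate
predicts GTV motion, which is exactly why the cine measurement is needed
— and the narrower margin reduces chest-wall and trachea–bronchus
maximum doses by 2.55 and 3.00 Gy on average.

See `vignettes/cinegate-methods.Rmd` for the model, parameter and design
documentation.

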