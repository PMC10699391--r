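# gimkit

Per-candidate **graphical item maps (GIMs)** for criterion-referenced
multiple-choice assessments, built on a from-scratch Rasch calibration.

A GIM is an individualised feedback chart for one exam candidate. Items
are arranged in columns by subject cluster, placed vertically by their
difficulty on the logit scale, and split around a central axis: items
the candidate answered correctly sit on the left, items answered
incorrectly on the right. A horizontal line marks the candidate's
ability estimate and, optionally, a second line marks the pass
standard, dividing the map into four quadrants. Incorrect items *below*
the pass standard — easy items missed — are the priority revision zone,
and subject clusters dominated by such items are flagged as potential
weaknesses (red), secure clusters as potential strengths (green). The
toolkit targets assessment programs such as the RANZCOG Fetal
Surveillance Education Program (FSEP): 60 dichotomous items over eight
subject clusters (PHYS, UPFH, NORM, BFHR, DECEL, MHR, UNCOM, RANZ)
covering cardiotocograph interpretation.

## The model

Responses are analysed with the dichotomous Rasch model,

    P(x_ni = 1) = exp(θ_n − δ_i) / (1 + exp(θ_n − δ_i)),

which places person abilities θ and item difficulties δ on one logit
scale. Item difficulties are estimated by **conditional maximum
likelihood (CML)**: conditioning on each person's raw score eliminates
the person parameters through the elementary symmetric functions
γ_r of the item easiness terms exp(−δ_i), so no ability distribution
needs to be assumed. Newton iterations with analytic gradient and
Fisher information run to a 1e-8 gradient tolerance under a mean-zero
identification constraint. Person abilities use **Warm's weighted
likelihood estimator (WLE)**, which is finite at zero and perfect raw
scores, so every candidate gets a map. The package also provides:

- infit/outfit mean-square item fit statistics for annual item review;
- the test characteristic curve and its inverse, converting a
  percentage pass mark into the logit pass line;
- a partial-credit (PCM) category mapping — attained score categories
  on the left, unattained on the right, each at its own threshold;
- a classical-test-theory variant that positions items by facility
  (percentage correct) on a 0–100 axis, plus FSEP practitioner-level
  classification (level 1: 55–65 %, level 3: > 75 %);
- deterministic SVG and plain-text renderers and a JSON report format;
- a seeded Rasch/PCM simulator and an FSEP-shaped synthetic fixture.

## Worked example

```r
library(gimkit)

fx   <- make_fsep_fixture(seed = 1)        # 60 items, 200 candidates
cal  <- calibrate_cml(fx$responses)
cal
#> <calibration_result> 60 items, converged = TRUE in 6 iterations

pers <- estimate_persons(fx$responses, cal$difficulties)
head(pers, 3)
#>   candidate_id raw_score    ability        se
#> 1        C0001        28 -0.2210090 0.3340735
#> 2        C0002        37  0.7814177 0.3380554
#> 3        C0003        24 -0.6688437 0.3374550

bank <- fx$bank
bank$items$difficulty <- unname(cal$difficulties[bank$items$item_id])
gim  <- build_gim("C0007", fx$responses, bank,
                  abilities = pers, pass_line = "75%")
gim
#> <gim_layout> candidate C0007: 60 items in 60 groups, theta = 0.668
#>   pass line at 1.754 logits; quadrant counts: lower_left=34 lower_right=13 upper_left=2 upper_right=11
#>   flags:  PHYS:weakness UPFH:strength NORM:strength DECEL:strength MHR:strength UNCOM:weakness RANZ:weakness

render_svg(gim, path = "C0007.svg")        # or render_text(gim)
write_gim_report(gim, "C0007.json")

classify_practitioner_level(100 * 42 / 60)  # 70 % -> level 2
#> [1] 2
```

Candidate C0007 sits at 0.668 logits, below the 75 % pass standard at
1.754 logits. Thirteen items easier than the pass standard were
answered incorrectly (`lower_right`), and three clusters accumulate
enough easy misses to be flagged for revision; five clusters with
secure correct answers are flagged as strengths.

A command-line wrapper covering `simulate`, `calibrate`, `persons`,
`facility`, `levels` and `gim` lives at `inst/cli/gimkit.R`:

```sh
Rscript inst/cli/gimkit.R gim --responses R.csv --bank calibrated.csv \
    --candidate C0005 --pass 75% --out map.svg --report map.json
```

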