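# teflow

Directed functional connectivity of multichannel EEG via lag-optimized,
nearest-neighbour transfer entropy — with the complete analysis chain
around it: signal conditioning, neutral-condition contrasts, bootstrap
channel selection, nonparametric group statistics with Rosenthal effect
sizes, a resampled classification specificity protocol, and a
repeated-measures sensitivity analysis. A seeded surrogate-EEG generator
with known directed couplings provides ground truth for every stage.

## Who this is for

Researchers analysing condition-dependent *directed* information flow
between EEG channels — e.g. which channels broadcast more information
under an odor/voice manipulation than under a neutral control — and
anyone who needs a tested, reproducible reference implementation of the
KSG transfer-entropy estimator with an information-transfer-delay scan.

## The core quantities

Transfer entropy from source $X$ to target $Y$ at delay $\mu$ is the
conditional mutual information

$$\mathrm{TE}_{X\to Y}(\mu) = I\!\left(Y_t; X_{t-\mu} \mid Y_{t-1},\dots,Y_{t-h_y}\right)
  \quad\text{(nats)},$$

estimated with the Kraskov–Stögbauer–Grassberger $k$-nearest-neighbour
construction ($\psi(k) - \langle\psi(n_{fz}{+}1) + \psi(n_{sz}{+}1) -
\psi(n_z{+}1)\rangle$, max-norm, $k = 4$). A brute-force scan over
$\mu = 0\dots50$ samples returns the maximal TE and its lag — the
information-transfer delay. Channels of interest are those whose
out-degree in the thresholded, neutral-contrasted, grand-averaged TE
matrix exceeds the bootstrap upper confidence bound of the mean degree;
channels surviving in every setting are the common channels carried into
group statistics (Kruskal–Wallis, Wilcoxon with $r = W/\sqrt{N}$) and a
hold-one-channel-per-class multinomial logistic-regression specificity
protocol (chance = 33.33% for three balanced settings).

## Worked example

Ground-truth recovery on a miniature study — two source channels (F3, C2)
drive three targets each only in the odorized settings:

```r
library(teflow)

design <- scaled_study_design(seed = 42, duration_samples = 600)
config <- study_config(design, settings = c("AM", "EM", "EF"),
                       lag_range = c(0L, 6L), B = 1000L, seed = 42L)
result <- run_study(config)

result$selections$EM
#> [1] "F3" "C2"
result$common
#> $common
#> [1] "F3" "C2"
#> $dropped
#> [1] "EF"
#> $retained
#> [1] "AM" "EM"
round(result$flows$EM$threshold, 3)
#> [1] 0.031
result$flows$EM$out_degree
#>  F3  F2  C2  P5  P6 PO3  O1  Cz
#>   3   2   3   0   0   0   0   0
```

The pipeline recovers exactly the two true sources (out-degree 3 each,
well above the bootstrap degree bound), drops the EF setting whose
contrast is identically null, and intersects the rest. A single pair
estimate:

```r
rec <- generate_recording(synth_design(
  n_channels = 2, channel_labels = c("F3", "P5"), rate = 100,
  duration_samples = 2000, ar_coeff = 0.5, noise_sd = 1,
  couplings = list(coupling_spec("F3", "P5", 5, 0.5, "EM")),
  n_subjects = 1, seed = 7), "S1", "EM")
lag_scan_te(rec$data["F3", ], rec$data["P5", ], te_config(), 0, 15)
#> TE = 0.14838 nats (delay 5, 1994 vectors)
```

The scan finds the planted 5-sample transfer delay (50 ms at 100 Hz).

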