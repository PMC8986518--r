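# ecotimescale

Timescale analysis for ecological and climatic time series, and for the
population consequences of environmental noise color.

The package is aimed at population ecologists and quantitative
biologists who ask *at which timescales* things happen: where in the
frequency domain the variance of a census series lives, whether two
co-occurring species are synchronized at long or short timescales,
whether that structure is statistically distinguishable from reordered
noise, and what reddened environmental fluctuations do to the
persistence of competing species.

## What it computes

**Spectra and cospectra.** FFT periodograms at the Fourier frequencies
f = k/n, smoothed with two clipped Daniell passes (spans 5 and 7) and
sum-normalized: a normalized spectrum sums to 1 and decomposes variance
by timescale; a normalized cospectrum sums to the Pearson correlation
R, so band sums partition correlation additively,

    R = R_1 + R_2 + R_3   (>12, 4–12, ≤4 months by default).

Significance comes from tandem-permutation surrogates: 2000 shared
reshuffles of the series destroy autocorrelation while preserving every
time-independent statistic; pointwise 95th (spectra) and 2.5th/97.5th
(cospectra) percentiles form the null bands. The spectral exponent — the
OLS slope of log S(f) vs log f — summarizes a spectrum's color (blue
> 0, white = 0, red < 0). A zero-phase band-stop filter (9–15 month
stop band) removes the annual cycle before temperature cospectra, and
harmonic regression tests annual vs annual+semiannual seasonal models.

**Colored noise.** `generate_noise()` synthesizes correlated bivariate
noise from any target spectral matrix (Cholesky factorization per
frequency, Hermitian symmetry, inverse FFT). The built-in linear family
S(f) = 0.5 + b(f − 0.25), b ∈ [−2, 2], sweeps blue → white → red at
constant variance 0.5 with constant cross-correlation 0.9.

**Stochastic competition.** The discrete-time Lotka–Volterra map

    N_i(t+1) = N_i(t) · exp[ r_i (K_i − N_i − comp_i)/K_i + σ_i ε_i(t) ]

with comp_1 = αN_2, comp_2 = βN_1, an absorbing extinction floor at 5%
of K, and reference parameters r = 0.3, K = 50, σ = 0.75, β = 0.25.
`extinction_sweep()` estimates extinction probabilities over a noise
color × competition grid (2000 replicates per cell);
`exponent_sweep()` and `replicate_spectral_summary()` show how
undercompensatory dynamics redden the environmental spectrum.

**Climate timescales.** Era-wise spectral exponents for station
networks (quadratic detrend → unsmoothed periodogram → exponent per
25-year era), paired era comparisons corrected for spatial
autocorrelation through an effective sample size (correlogram-model
estimator), and a station-averaged ("mean field") generalized Morse
wavelet (γ = 3, time-bandwidth 60) with tandem-surrogate hot-spot
masks and a cone of influence.

**Synthetic data.** Generators for census pairs, monthly temperature
series, and spatially correlated station networks with prescribed
era-varying residual spectral exponents — every analysis stage is
testable offline.

## Worked example

```r
library(ecotimescale)

# a synthetic 140-month bivariate census with target correlation 0.58
d <- synth_census(seed = 42)
cs <- est_cospectrum(d, count_species1, count_species2, smooth = FALSE)
partition_correlation(cs, c(12, 4))
#>   band min_period max_period correlation n_freq
#> 1  >12         12        Inf      0.0746     11
#> 2 4-12          4         12      0.3044     23
#> 3  <=4          0          4      0.1909     36
```

The three band correlations sum to the total Pearson correlation of
the two count series (0.57 for this seed): about 0.07 of it lives at
timescales longer than a year, 0.30 at 4–12 months, 0.19 below 4
months.

```r
sw <- extinction_sweep(alpha_values = c(0.25, 0.75),
                       slopes = c(2, 0, -2), n_reps = 2000, seed = 42)
sw
#>   alpha slope p_ext_native p_ext_invader se_native se_invader
#> 1  0.25     2       0.0000        0.0000   0.00000    0.00000
#> 2  0.25     0       0.1550        0.1480   0.00809    0.00794
#> 3  0.25    -2       0.5690        0.5600   0.01107    0.01110
#> 4  0.75     2       0.0275        0.0000   0.00366    0.00000
#> 5  0.75     0       0.8500        0.0955   0.00798    0.00657
#> 6  0.75    -2       0.9820        0.4680   0.00297    0.01116
```

Blue noise (slope +2) is harmless at either competition intensity;
reddening the same amount of environmental variance (slope −2) drives
both symmetric competitors to ~56% extinction risk, and a native
species facing a stronger competitor (α = 0.75) from ~3% under blue
noise to near-certain extinction under red noise. `autoplot(sw)` draws
the sweep.

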