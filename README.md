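# lockinamp

Digital lock-in amplification for fluorescence biosensing, in R.

Low-cost fluorimeters recover weak fluorescence from noise and ambient
light by modulating the excitation LED at a fixed frequency and
demodulating the photodetector signal synchronously. `lockinamp`
implements that whole signal chain in software:

* **`lockin_core`** — a streaming dual-phase lock-in demodulator. With
  sample rate `fs` and modulation divisor `m` (modulation frequency
  `f0 = fs/m`), each sample `S(n)` is mixed with quadrature references
  `cos(2*pi*n/m)` and `sin(2*pi*n/m)`, each product passes through two
  cascaded exponential moving-average filters
  `X(n) = X(n-1) + alpha*[X0(n) - X(n-1)]`, and the amplitude
  `R = sqrt(X^2 + Y^2)` is emitted every 0.1 s. Defaults: `fs` = 200 kHz,
  `m` = 488 (`f0` = 409.84 Hz), `alpha` = 7.85e-6 (0.25-Hz cut-off,
  0.64-s time constant).
* **`instrument_sim`** — a synthetic photodetector front end: saturable
  dose response with modulated background leakage, square-wave LED
  modulation with turn-on lag, ambient/mains/white-noise interference,
  16-Hz DC-compensation high-pass, 94-kHz anti-aliasing low-pass, and
  12-bit quantisation. Deterministic per seed, so the demodulator and
  calibration statistics are testable without hardware.
* **`calibration`** — assay characterisation: background subtraction,
  through-origin sensitivity fit (`R2cor = m*c`), 2-sigma detection
  limit `LOD = 2*sigma_blank/m`, linear-range bound and dynamic range.
* **CLI** — a thin command-line wrapper
  (`inst/cli/lockinamp`) with `simulate`, `demod`, `calibrate` and
  `characterize` subcommands over CSV/JSON files.

## Worked example

Simulate a dilution series on the instrument's default operating point,
then calibrate it:

```r
library(lockinamp)

cfg <- demod_config()                      # 200 kHz, m = 488, fc = 0.25 Hz
em  <- emission_model(sensitivity = 1e5)   # 1e5 a.u./M, quench scale 0.74 mM
fe  <- front_end_model()                   # 16 Hz HP, 94 kHz LP, 12-bit ADC

rec <- simulate_dilution(c(0.5, 1, 2, 4, 8) * 1e-6, em, fe, cfg, seed = 1)
calibrate(rec)
```

```
Calibration result
  sensitivity      : 3.878e+07 a.u./M
  R^2              : 1.0000
  2-sigma LOD      : 1.66e-10 M
  linear range max : 8e-06 M
  dynamic range    : 4.818e+04
  blank            : 19.5731 +/- 0.0032 a.u. (5 points fitted)
```

The sensitivity is in ADC-count units per molar: the 1e5 V/M emission
truth times the converter gain (4095 counts / 3.3 V) divided by pi (a
0-to-A square wave carries a first harmonic of `2A/pi`, and the
demodulator reports half of it). The blank of ~19.6 a.u. is the
modulated background leakage — it is what the background subtraction
removes — and the LOD says the noise floor corresponds to ~0.16 nM at
this noise setting. The linear range ends at the highest concentration
still within 5% of the fitted line.

Single-stream demodulation works on any numeric vector or CSV stream:

```r
n  <- 0:1999999
sq <- modulation_waveform(n, 488)       # unit square wave at f0
tail(demodulate(sq, cfg)$values, 1)     # 0.3183111  (= 1/pi)
```

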