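# pcgdenoise

Low-noise processing of heart-sound (phonocardiogram, PCG) recordings in
R: a digital emulation of an analog conditioning front end, wavelet
shrinkage denoising, and a frame-spectral noise-level statistic for
comparing two recordings — plus a seeded synthetic PCG and noise
generator so the whole chain is testable without clinical data.

Intended users: biomedical-signal researchers and engineers prototyping
electronic stethoscope pipelines, and anyone who needs a reproducible,
fully parameterized heart-sound denoising bench.

## What it computes

**Front end.** A causal 4th-order Butterworth low-pass at 700 Hz (the
upper edge of the heart-sound band) followed by a twin-T style notch at
the mains frequency (50 Hz default, 60 Hz configurable), both designed
by bilinear transform with prewarping.

**Wavelet denoiser.** A level-4 discrete wavelet transform with the
Daubechies `db10` wavelet splits a 2000 Hz signal into the bands
0–62.5, 62.5–125, 125–250, 250–500 and 500–1000 Hz. The 500–1000 Hz
band lies above the heart-sound range and is eliminated (hard threshold,
infinite `T`). The remaining bands are soft thresholded,

```
f_S(c) = sign(c) * (|c| - th)  if |c| >= th,  else 0
```

with the minimax threshold computed from the finest-scale coefficients
`w` and the signal length `N`:

```
sigma = median(|w|) / 0.6745
th    = sigma * (0.3936 + 0.10829 * log2(N))   for N > 32   (else 0)
```

**ENR.** Each recording is peak normalized and cut into 5 frames; per
frame, the variance of the two-sided FFT power-spectrum values is taken,
averaged over frames into a noise-power estimate `sigma_hat_sq`; the
estimated noise ratio is

```
ENR = 100% * sigma_hat_sq(test) / sigma_hat_sq(reference)
```

## Worked example

```r
library(pcgdenoise)

clean <- generate_pcg(pcg_config(seed = 42))          # 15 s @ 2000 Hz, 60 bpm
noise <- generate_noise(noise_spec("white", seed = 43), 30000, 2000)
noisy <- mix_at_snr(clean, noise, 0)                  # exact 0 dB SNR

den <- pcg_denoise(noisy)                             # level-4 db10 shrinkage
cat(sprintf("input SNR: %.2f dB\n", measure_snr(clean, noisy)))
cat(sprintf("output SNR: %.2f dB\n", measure_snr(clean, den)))
attr(den, "denoise_info")
```

prints

```
input SNR: 0.00 dB
output SNR: 10.52 dB
<threshold_result: sigma = 0.148447, N = 30000, threshold = 0.297512>
```

The denoiser recovered about 10.5 dB of SNR. `sigma` is the
median-absolute-deviation noise scale estimated from the 500–1000 Hz
coefficients (the mixed noise had RMS ≈ 0.149, so the estimate is on
target), and the threshold follows the minimax rule at `N = 30000`.

The same pipeline is scriptable from a shell via the installed
`pcgtools` launcher:

```sh
pcgtools simulate --out noisy.wav --noise knocking --snr-db 5 --seed 7
pcgtools pipeline noisy.wav results/      # filter -> denoise -> evaluate
pcgtools evaluate results/denoised.wav noisy.wav --report enr.csv
```

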