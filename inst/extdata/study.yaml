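# Default synthetic replicate-precision study.
#
# Five quintuplicate conditions on one spherical phantom, mirroring the
# classical sources of variability in CT-based virtual bone modelling:
# a baseline protocol, re-segmentation with small and large threshold
# perturbations (stand-ins for intra- and inter-observer variability,
# whose only free parameter in this chain is the interactive threshold),
# a tripled slice thickness, and a halved exposure. Each non-baseline
# condition is compared against the baseline.
phantom:
  kind: sphere
  dimensions: 20
  resolution: 4
conditions:
  baseline:
    n_replicates: 5
    mode: volume
    imaging: {spacing: 0.7, slice_thickness: 0.9, exposure_fraction: 1.0,
              noise_sigma_ref: 40}
    segmentation: {lower: 200, upper: 10000, close_radius: 1.4,
                   smooth_sigma: 0.7}
  intra_observer:
    n_replicates: 5
    mode: volume
    imaging: {spacing: 0.7, slice_thickness: 0.9, exposure_fraction: 1.0,
              noise_sigma_ref: 40}
    segmentation: {lower: 200, upper: 10000, close_radius: 1.4,
                   smooth_sigma: 0.7, threshold_jitter_sd: 5}
  inter_observer:
    n_replicates: 5
    mode: volume
    imaging: {spacing: 0.7, slice_thickness: 0.9, exposure_fraction: 1.0,
              noise_sigma_ref: 40}
    segmentation: {lower: 200, upper: 10000, close_radius: 1.4,
                   smooth_sigma: 0.7, threshold_jitter_sd: 15}
  thick_slice:
    n_replicates: 5
    mode: volume
    imaging: {spacing: 0.7, slice_thickness: 2.7, exposure_fraction: 1.0,
              noise_sigma_ref: 40}
    segmentation: {lower: 200, upper: 10000, close_radius: 1.4,
                   smooth_sigma: 0.7}
  low_exposure:
    n_replicates: 5
    mode: volume
    imaging: {spacing: 0.7, slice_thickness: 0.9, exposure_fraction: 0.5,
              noise_sigma_ref: 40}
    segmentation: {lower: 200, upper: 10000, close_radius: 1.4,
                   smooth_sigma: 0.7}
comparisons:
  - [baseline, intra_observer]
  - [baseline, inter_observer]
  - [baseline, thick_slice]
  - [baseline, low_exposure]
thresholds: [0.07, 0.175, 0.35, 0.7]
estimator: rms
seed: 20240917
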