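# Study conditions for the synthetic texture-robustness experiment.
# Two tissue-density arms, both Wiener-filter arms, the full quantization /
# ROI / offset grid. Slabs are 240 x 240 so that every ROI size up to 100
# tiles at least four windows.
densities: [0.25, 0.5]
n_images: 2
height: 240
width: 240
correlation_length: 4
tissue_values:
  adipose: 1200
  fibroglandular: 900
quantum_gain: 1
electronic_sigma: 15
filter_arms: [false, true]
wiener_window: 5
quantizations: [8, 32, 64, 128]
roi_sizes: [10, 25, 50, 100]
offsets: [1, 5, 7, 10, 15, 20]
angles: [0, 45, 90, 135]
normalization_mode: fixed_roi
base_seed: 20260920
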