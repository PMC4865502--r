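# Calibrated generative presets for the three diagnostic groups.
# Expected task metrics under these parameters approximate the published
# group means (identification, gross localization error, swap rate).
# p_ident: probability of correct 2AFC identification per load/delay/block.
# p_swap: probability a correct 3-item report anchors on a non-target.
# sigma_deg: isotropic report noise (deg). p_guess: uniform-guess mixture.
# volume_swap_slope: logit(p_swap) change per cm^3 hippocampal volume
# above the group mean (carriers only).
groups:
  control:
    label: control
    sigma_deg: 2.6
    p_guess: 0.04
    p_ident:
      - {n_items: 1, delay_s: 1, block: 1, p: 0.99}
      - {n_items: 1, delay_s: 4, block: 1, p: 0.97}
      - {n_items: 1, delay_s: 1, block: 2, p: 0.99}
      - {n_items: 1, delay_s: 4, block: 2, p: 0.98}
      - {n_items: 3, delay_s: 1, block: 1, p: 0.91}
      - {n_items: 3, delay_s: 4, block: 1, p: 0.87}
      - {n_items: 3, delay_s: 1, block: 2, p: 0.92}
      - {n_items: 3, delay_s: 4, block: 2, p: 0.89}
    p_swap:
      - {delay_s: 1, block: 1, p: 0.13}
      - {delay_s: 4, block: 1, p: 0.16}
      - {delay_s: 1, block: 2, p: 0.11}
      - {delay_s: 4, block: 2, p: 0.14}
    hippo_volume_mean: 5.8
    hippo_volume_sd: 0.64
    tiv_mean: 1450
    tiv_sd: 140
    age_mean: 36.9
    age_sd: 4.1
    sex_p_male: 0.50
    nart_mean: 31
    nart_sd: 9.0
    volume_swap_slope: 0
  asymptomatic:
    label: asymptomatic
    sigma_deg: 2.6
    p_guess: 0.05
    p_ident:
      - {n_items: 1, delay_s: 1, block: 1, p: 0.99}
      - {n_items: 1, delay_s: 4, block: 1, p: 0.97}
      - {n_items: 1, delay_s: 1, block: 2, p: 0.99}
      - {n_items: 1, delay_s: 4, block: 2, p: 0.98}
      - {n_items: 3, delay_s: 1, block: 1, p: 0.89}
      - {n_items: 3, delay_s: 4, block: 1, p: 0.85}
      - {n_items: 3, delay_s: 1, block: 2, p: 0.90}
      - {n_items: 3, delay_s: 4, block: 2, p: 0.87}
    p_swap:
      - {delay_s: 1, block: 1, p: 0.13}
      - {delay_s: 4, block: 1, p: 0.26}
      - {delay_s: 1, block: 2, p: 0.11}
      - {delay_s: 4, block: 2, p: 0.17}
    hippo_volume_mean: 6.0
    hippo_volume_sd: 0.69
    tiv_mean: 1450
    tiv_sd: 140
    age_mean: 37.2
    age_sd: 4.4
    sex_p_male: 0.25
    nart_mean: 28.3
    nart_sd: 9.3
    volume_swap_slope: -0.55
  symptomatic:
    label: symptomatic
    sigma_deg: 3.2
    p_guess: 0.09
    p_ident:
      - {n_items: 1, delay_s: 1, block: 1, p: 0.96}
      - {n_items: 1, delay_s: 4, block: 1, p: 0.94}
      - {n_items: 1, delay_s: 1, block: 2, p: 0.97}
      - {n_items: 1, delay_s: 4, block: 2, p: 0.95}
      - {n_items: 3, delay_s: 1, block: 1, p: 0.80}
      - {n_items: 3, delay_s: 4, block: 1, p: 0.75}
      - {n_items: 3, delay_s: 1, block: 2, p: 0.81}
      - {n_items: 3, delay_s: 4, block: 2, p: 0.775}
    p_swap:
      - {delay_s: 1, block: 1, p: 0.28}
      - {delay_s: 4, block: 1, p: 0.34}
      - {delay_s: 1, block: 2, p: 0.27}
      - {delay_s: 4, block: 2, p: 0.33}
    hippo_volume_mean: 5.2
    hippo_volume_sd: 0.55
    tiv_mean: 1450
    tiv_sd: 140
    age_mean: 43.0
    age_sd: 5.0
    sex_p_male: 0.50
    nart_mean: 24
    nart_sd: 9.0
    volume_swap_slope: -0.55
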