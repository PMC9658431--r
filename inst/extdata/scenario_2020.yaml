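# Synthetic greenhouse tomato season preset, 2020-like.
year: "2020"
start: 2020-03-04
end: 2020-07-07
stages:
  initial:     {start: 2020-03-04, end: 2020-03-25}
  development: {start: 2020-03-26, end: 2020-05-05}
  middle:      {start: 2020-05-06, end: 2020-06-16}
  late:        {start: 2020-06-17, end: 2020-07-07}
stage_means:          # Rn: W/m2 (6:00-18:00 mean); Ta: C; VPD: kPa; u2: m/s
  initial:     {Rn: 103.32, Ta: 18.88, VPD: 0.791, u2: 0.114}
  development: {Rn: 131.53, Ta: 20.82, VPD: 0.700, u2: 0.112}
  middle:      {Rn: 142.53, Ta: 25.48, VPD: 1.172, u2: 0.145}
  late:        {Rn: 154.09, Ta: 27.03, VPD: 0.710, u2: 0.138}
diurnal:
  sunrise: 6
  sunset: 19
  peak_hour: 13
  lag_hours: 1
  rn_night: -5.0
  ta_amp: 5.0
  vpd_amp_frac: 0.8
  u2_amp: 0.08
crop:
  lai_peak: 3.46
  height_peak: 145
soil:
  theta_s: 0.32
  theta_w: 0.09
  theta0: 0.30
  trigger_se: 0.79
  refill_frac: 0.95
  drydown_initial: 0.025
  drydown_later: 0.06
  sensor_sd: 0.002
noise:
  rn_day_cv: 0.12
  rn_hour_cv: 0.03
  ta_sd: 0.8
  vpd_sd: 0.06
  u2_sd: 0.04
  rho: 0.7
  obs_cv: 0.05
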