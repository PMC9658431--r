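# Synthetic greenhouse tomato season preset, 2019-like.
# Stage calendar and per-stage climate targets follow the measured
# two-season experiment the generators emulate.
year: "2019"
start: 2019-03-12
end: 2019-07-13
stages:
  initial:     {start: 2019-03-12, end: 2019-04-02}
  development: {start: 2019-04-03, end: 2019-05-11}
  middle:      {start: 2019-05-12, end: 2019-06-20}
  late:        {start: 2019-06-21, end: 2019-07-13}
stage_means:          # Rn: W/m2 (6:00-18:00 mean); Ta: C; VPD: kPa; u2: m/s
  initial:     {Rn: 114.81, Ta: 19.19, VPD: 1.031, u2: 0.118}
  development: {Rn: 125.65, Ta: 21.26, VPD: 0.716, u2: 0.120}
  middle:      {Rn: 149.92, Ta: 26.39, VPD: 1.419, u2: 0.102}
  late:        {Rn: 148.44, Ta: 28.23, VPD: 1.296, u2: 0.089}
diurnal:
  sunrise: 6            # hour Rn starts to rise
  sunset: 19            # hour Rn returns to zero
  peak_hour: 13         # Rn maximum (13:00-14:00 in the emulated data)
  lag_hours: 1          # Ta and VPD maxima lag Rn by 1 h
  rn_night: -5.0        # nighttime net radiation, W/m2
  ta_amp: 5.0           # diurnal air-temperature amplitude, C
  vpd_amp_frac: 0.8     # diurnal VPD amplitude as fraction of stage mean
  u2_amp: 0.08          # daytime ventilation bump on wind speed, m/s
crop:
  lai_peak: 3.46        # cm2/cm2, mid-middle-stage maximum
  height_peak: 145      # cm
soil:
  theta_s: 0.32         # saturated topsoil water content, cm3/cm3
  theta_w: 0.09         # wilting point, cm3/cm3
  theta0: 0.30          # content after the transplanting irrigation
  trigger_se: 0.79      # effective saturation that triggers drip events
  refill_frac: 0.95     # refill toward refill_frac * theta_s
  drydown_initial: 0.025  # d^-1, sparse-canopy drydown rate
  drydown_later: 0.06     # d^-1, full-canopy drydown rate
  sensor_sd: 0.002      # sensor noise, cm3/cm3
noise:
  rn_day_cv: 0.12       # day-to-day lognormal cloudiness
  rn_hour_cv: 0.03
  ta_sd: 0.8            # C
  vpd_sd: 0.06          # kPa
  u2_sd: 0.04           # m/s
  rho: 0.7              # AR(1) autocorrelation
  obs_cv: 0.05          # lysimeter-like observation noise
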