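# Smoke-scale study configuration: 2 seasonal controls, 3 members, 8x8 grid.
# Scale members/nlat/nlon/years up for production-style runs.
nlat: 8
nlon: 8
years: [1999, 2008]
members: 3
seed_base: 70
seasons: [MAM, JJA]
regime: wet
scenario:
  noise_sd: 0.15
  seed: 7
params:
  w_air: 0.5
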