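species,n,pct_visiting,winter_days_mean,winter_days_sd,n_locations_mean,n_locations_sd,in_region_mean,in_region_sd,proportion_mean,proportion_sd
lesser black-backed gull,7,71.4,208.4,27.4,151.1,20.8,21.0,24.0,0.09,0.10
northern gannet,34,58.8,93.6,13.4,89.6,15.4,25.7,29.8,0.26,0.29
great skua,16,25,92,NA,91.9,0.4,11.1,21.8,0.12,0.24
Cory's shearwater,19,57.9,133.9,29.9,131.5,27.4,13.8,23.2,0.10,0.18
Scopoli's shearwater,9,100,104.5,40.8,102.3,39.6,35.4,36.9,0.35,0.28
Sabine's gull,7,100,287.9,12.7,228.6,18.6,22.3,3.1,0.08,0.01
south polar skua,19,100,237.2,35.1,176.3,21.6,8.7,14.3,0.04,0.07
common tern,12,100,254.3,67.0,181.3,64.0,62.8,51.8,0.24,0.22
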