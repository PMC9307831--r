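name: alpine
latitude: 40.05
elevation: 3480
mean_annual_temp: 271.7
seasonal_amplitude: 10
diurnal_amplitude: 8
annual_precip: 950
wet_day_fraction: 0.4
cloud_persistence: 0.92
snow_threshold_temp: 274.15
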