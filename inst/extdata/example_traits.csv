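species,realm,trait,temperature_C,rate
freshwater_sp01,freshwater,ingestion_rate,7.14242,0.207605
freshwater_sp01,freshwater,ingestion_rate,7.14242,0.264868
freshwater_sp01,freshwater,ingestion_rate,9.16642,0.330915
freshwater_sp01,freshwater,ingestion_rate,9.16642,0.351115
freshwater_sp01,freshwater,ingestion_rate,11.1904,0.429844
freshwater_sp01,freshwater,ingestion_rate,11.1904,0.508745
freshwater_sp01,freshwater,ingestion_rate,13.2144,0.585479
freshwater_sp01,freshwater,ingestion_rate,13.2144,0.502564
freshwater_sp01,freshwater,ingestion_rate,15.2384,0.678317
freshwater_sp01,freshwater,ingestion_rate,15.2384,0.599539
freshwater_sp01,freshwater,ingestion_rate,17.2624,0.777157
freshwater_sp01,freshwater,ingestion_rate,17.2624,0.776165
freshwater_sp01,freshwater,ingestion_rate,19.2864,0.768265
freshwater_sp01,freshwater,ingestion_rate,19.2864,0.865883
freshwater_sp01,freshwater,ingestion_rate,21.3104,0.756586
freshwater_sp01,freshwater,ingestion_rate,21.3104,0.769694
freshwater_sp01,freshwater,ingestion_rate,23.3344,0.640479
freshwater_sp01,freshwater,ingestion_rate,23.3344,0.61899
freshwater_sp01,freshwater,ingestion_rate,25.3584,0.533529
freshwater_sp01,freshwater,ingestion_rate,25.3584,0.546922
freshwater_sp01,freshwater,ingestion_rate,27.3824,0.394173
freshwater_sp01,freshwater,ingestion_rate,27.3824,0.375923
freshwater_sp01,freshwater,ingestion_rate,29.4064,0.282167
freshwater_sp01,freshwater,ingestion_rate,29.4064,0.238189
marine_sp02,marine,ingestion_rate,16.6424,0
marine_sp02,marine,ingestion_rate,16.6424,0
marine_sp02,marine,ingestion_rate,18.135,0
marine_sp02,marine,ingestion_rate,18.135,0
marine_sp02,marine,ingestion_rate,19.6276,0
marine_sp02,marine,ingestion_rate,19.6276,0
marine_sp02,marine,ingestion_rate,21.1202,2.38181
marine_sp02,marine,ingestion_rate,21.1202,1.94545
marine_sp02,marine,ingestion_rate,22.6129,4.01328
marine_sp02,marine,ingestion_rate,22.6129,4.4372
marine_sp02,marine,ingestion_rate,24.1055,5.44399
marine_sp02,marine,ingestion_rate,24.1055,5.40648
marine_sp02,marine,ingestion_rate,25.5981,5.94102
marine_sp02,marine,ingestion_rate,25.5981,6.71357
marine_sp02,marine,ingestion_rate,27.0907,5.64334
marine_sp02,marine,ingestion_rate,27.0907,5.56811
marine_sp02,marine,ingestion_rate,28.5833,4.11948
marine_sp02,marine,ingestion_rate,28.5833,3.88152
marine_sp02,marine,ingestion_rate,30.0759,1.37391
marine_sp02,marine,ingestion_rate,30.0759,1.39795
marine_sp02,marine,ingestion_rate,31.5685,0
marine_sp02,marine,ingestion_rate,31.5685,0
marine_sp02,marine,ingestion_rate,33.0611,0
marine_sp02,marine,ingestion_rate,33.0611,0
terrestrial_sp03,terrestrial,ingestion_rate,21.7328,0.462698
terrestrial_sp03,terrestrial,ingestion_rate,21.7328,0.747409
terrestrial_sp03,terrestrial,ingestion_rate,23.088,1.01112
terrestrial_sp03,terrestrial,ingestion_rate,23.088,1.10886
terrestrial_sp03,terrestrial,ingestion_rate,24.4432,1.76939
terrestrial_sp03,terrestrial,ingestion_rate,24.4432,1.91578
terrestrial_sp03,terrestrial,ingestion_rate,25.7984,2.62105
terrestrial_sp03,terrestrial,ingestion_rate,25.7984,2.60046
terrestrial_sp03,terrestrial,ingestion_rate,27.1537,2.97075
terrestrial_sp03,terrestrial,ingestion_rate,27.1537,2.80725
terrestrial_sp03,terrestrial,ingestion_rate,28.5089,3.10829
terrestrial_sp03,terrestrial,ingestion_rate,28.5089,3.23521
terrestrial_sp03,terrestrial,ingestion_rate,29.8641,3.37332
terrestrial_sp03,terrestrial,ingestion_rate,29.8641,3.06831
terrestrial_sp03,terrestrial,ingestion_rate,31.2194,3.14043
terrestrial_sp03,terrestrial,ingestion_rate,31.2194,3.11038
terrestrial_sp03,terrestrial,ingestion_rate,32.5746,2.87221
terrestrial_sp03,terrestrial,ingestion_rate,32.5746,3.01575
terrestrial_sp03,terrestrial,ingestion_rate,33.9298,2.32244
terrestrial_sp03,terrestrial,ingestion_rate,33.9298,2.34199
terrestrial_sp03,terrestrial,ingestion_rate,35.2851,1.56746
terrestrial_sp03,terrestrial,ingestion_rate,35.2851,1.53305
terrestrial_sp03,terrestrial,ingestion_rate,36.6403,0.952143
terrestrial_sp03,terrestrial,ingestion_rate,36.6403,1.04784
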