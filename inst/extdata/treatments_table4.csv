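treatment_id,sediment_id,spike_level,medium,ph,orp,toc,avs,clay,silt,sand,cec,log_kd,ow_ni,tr_ni
WB-0,WB,0,sediment,6.63,-87,10.40,38,24.7,68.3,7.0,44.1,4.56,0.93,59.7
WB-1,WB,1,sediment,6.62,-79,11.20,25,21.1,66.1,12.8,42.5,4.37,4.62,156
WB-2,WB,2,sediment,6.65,-85,9.70,26,20.6,66.5,12.9,37.4,4.24,8.57,369
WB-3,WB,3,sediment,6.65,-89,11.20,26,24.8,63.6,11.6,44.7,4.20,26.0,1040
WB-4,WB,4,sediment,6.62,-86,10.50,18,21.0,63.5,15.5,39.7,4.13,98.1,2680
WB-5,WB,5,sediment,6.65,-80,10.20,12,23.5,66.3,10.2,37.4,3.92,122,7660
SR-0,SR,0,sediment,7.03,-169,0.40,0.94,6.9,13.6,79.5,5.5,3.56,1.70,8.9
SR-1,SR,1,sediment,6.96,-171,0.60,0.90,7.9,15.7,76.4,6.4,3.56,11,56.6
SR-2,SR,2,sediment,7.03,-165,0.40,0.77,7.1,12.7,80.2,5.0,3.55,67.7,122
SR-3,SR,3,sediment,7.03,-162,0.40,0.70,8.4,13.9,77.7,6.3,3.55,164,213
SR-4,SR,4,sediment,7.06,-156,0.30,0.51,8.1,12.2,79.7,5.0,3.57,801,411
SR-5,SR,5,sediment,7.03,-152,0.40,0.46,7.9,14.2,77.9,5.4,3.57,5700,941
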