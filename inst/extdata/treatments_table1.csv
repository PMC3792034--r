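treatment_id,sediment_id,spike_level,medium,ph,orp,toc,avs,clay,silt,sand,cec,log_kd,tr_ni
SR-0,SR,0,sediment,7.03,-169,0.40,0.94,6.9,13.6,79.5,5.5,3.56,8.9
STJ-0,STJ,0,sediment,7.28,-186,1.9,3.78,7.9,10.3,81.8,11.3,3.979,8
P30-0,P30,0,sediment,6.87,-168,1.8,12.37,24.2,66.0,9.8,19.0,4.248,14
DOW-0,DOW,0,sediment,6.90,-155,1.2,1.04,6.0,7.0,87.0,6.4,3.794,6
RR2-0,RR2,0,sediment,6.98,-188,3.5,6.06,8.1,19.8,72.1,14.5,4.164,12
STM-0,STM,0,sediment,7.14,-189,8.1,24.70,8.4,37.5,54.1,29.1,4.349,18
RR3-0,RR3,0,sediment,7.02,-179,7.2,7.98,5.9,19.5,74.6,29.3,3.857,9
WB-0,WB,0,sediment,6.63,-87,10.40,38,24.7,68.3,7.0,44.1,4.56,59.7
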