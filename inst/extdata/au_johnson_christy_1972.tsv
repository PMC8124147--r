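# Gold (Au) complex refractive index, digitized from the
# Johnson & Christy (1972) bulk-film measurements.
# wavelength_nm = 1239.84193 / photon energy (eV); sorted ascending.
wavelength_nm	n	k
187.85	1.150	1.189
191.63	1.180	1.203
195.25	1.200	1.226
199.33	1.210	1.251
203.25	1.240	1.277
207.33	1.270	1.304
211.94	1.300	1.350
216.38	1.300	1.387
221.40	1.300	1.427
226.25	1.310	1.460
231.31	1.300	1.497
237.06	1.320	1.536
242.63	1.320	1.577
248.96	1.330	1.631
255.11	1.330	1.688
261.57	1.350	1.749
268.95	1.380	1.803
276.13	1.430	1.847
284.37	1.470	1.869
292.42	1.490	1.878
300.93	1.530	1.889
310.74	1.530	1.893
320.37	1.540	1.898
331.51	1.480	1.883
342.50	1.480	1.871
354.24	1.500	1.866
367.91	1.480	1.895
381.49	1.460	1.933
397.39	1.470	1.952
413.28	1.460	1.958
430.50	1.450	1.948
450.85	1.380	1.914
471.42	1.310	1.849
495.94	1.040	1.833
520.94	0.620	2.081
548.60	0.430	2.455
582.09	0.290	2.863
616.84	0.210	3.272
659.49	0.140	3.697
704.46	0.130	4.103
756.00	0.140	4.542
821.09	0.160	5.083
891.97	0.170	5.663
984.00	0.220	6.350
1087.58	0.270	7.150
1215.53	0.350	8.145
1393.08	0.430	9.519
1610.18	0.560	11.210
1937.25	0.920	13.780
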