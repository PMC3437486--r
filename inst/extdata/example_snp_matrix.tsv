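freq_bin	>500	101-500	11-100	3-10
<0.1	389	751	2109	158
0.10-0.19	107	414	2431	500
0.20-0.29	17	123	3856	827
0.30-0.39	4	47	1478	992
0.40-0.49	1	13	746	828
0.50-0.59	8	18	502	1442
0.60-0.69	0	17	297	1361
0.70-0.79	0	1	85	374
0.80-0.89	0	0	55	166
0.90-1.0	0	0	40	1463
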