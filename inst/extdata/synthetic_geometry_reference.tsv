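complex_id	crossing_angle	incident_angle	x_pos	y_pos
demo_01	61.8	0.7	5.7	-2.5
demo_02	36	1.7	-3.8	-0.3
demo_03	54	10.2	2.5	-1.8
demo_04	54.9	12.7	4.7	-3.4
demo_05	42.9	12	5.1	-0.6
demo_06	55.1	4.4	2.2	-1
demo_07	40.8	9.2	-0.1	1.1
demo_08	35.2	12.2	4.5	-1.5
demo_09	63.8	0	0.5	2.5
demo_10	26	0.3	0.2	3.1
demo_11	65.1	6.6	-1.2	1.8
demo_12	67.7	4.4	2.5	-1.5
demo_13	55.2	2.6	2.5	-1.7
demo_14	45.8	14.6	-3.4	1.2
demo_15	42.5	10.1	3.4	-2.4
demo_16	62.1	10.2	0.5	1.1
demo_17	25.5	0.8	0.9	-0.4
demo_18	63.2	22	3.5	-1.5
demo_19	26.6	25	3.2	1.7
demo_20	34.8	29	-3.8	-1.7
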