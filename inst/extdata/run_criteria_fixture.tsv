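piece	duration_s	net_nm	speed_nm_s	expected_kind
1	0.50	300	600	run
2	0.75	30	40	pause
3	4.55	250	55	run
4	0.25	150	600	subthreshold
5	0.20	400	2000	subthreshold
6	1.00	45	45	pause
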