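site	pos	A	C	G	T
donor	 1	0.330	0.370	0.18	0.120
donor	 2	0.600	0.130	0.14	0.130
donor	 3	0.080	0.040	0.81	0.070
donor	 4	0.010	0.010	0.97	0.010
donor	 5	0.010	0.010	0.01	0.970
donor	 6	0.600	0.030	0.34	0.030
donor	 7	0.700	0.080	0.12	0.100
donor	 8	0.080	0.050	0.82	0.050
donor	 9	0.150	0.170	0.19	0.490
acceptor	 1	0.100	0.350	0.10	0.450
acceptor	 2	0.100	0.350	0.10	0.450
acceptor	 3	0.100	0.350	0.10	0.450
acceptor	 4	0.100	0.350	0.10	0.450
acceptor	 5	0.100	0.350	0.10	0.450
acceptor	 6	0.100	0.350	0.10	0.450
acceptor	 7	0.100	0.350	0.10	0.450
acceptor	 8	0.100	0.350	0.10	0.450
acceptor	 9	0.100	0.350	0.10	0.450
acceptor	10	0.100	0.350	0.10	0.450
acceptor	11	0.100	0.350	0.10	0.450
acceptor	12	0.100	0.350	0.10	0.450
acceptor	13	0.100	0.350	0.10	0.450
acceptor	14	0.100	0.350	0.10	0.450
acceptor	15	0.100	0.350	0.10	0.450
acceptor	16	0.100	0.350	0.10	0.450
acceptor	17	0.100	0.350	0.10	0.450
acceptor	18	0.100	0.650	0.05	0.200
acceptor	19	0.970	0.010	0.01	0.010
acceptor	20	0.010	0.010	0.97	0.010
acceptor	21	0.210	0.150	0.49	0.150
acceptor	22	0.250	0.350	0.20	0.200
acceptor	23	0.233	0.233	0.30	0.234
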