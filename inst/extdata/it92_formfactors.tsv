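# IT92 4-Gaussian atomic form-factor coefficients: f0(s) = sum a_i exp(-b_i s^2) + c, s = sin(theta)/lambda
# element	a1	a2	a3	a4	b1	b2	b3	b4	c
S	6.905300	5.203400	1.437900	1.586300	1.467900	22.215100	0.253600	56.172000	0.866900
Ca	8.626600	7.387300	1.589900	1.021100	10.442100	0.659900	85.748400	178.437000	1.375100
Mn	11.281900	7.357300	3.019300	2.244100	5.340900	0.343200	17.867400	83.754300	1.089600
Fe	11.769500	7.357300	3.522200	2.304500	4.761100	0.307200	15.353500	76.880500	1.036900
Ni	12.837600	7.292000	4.443800	2.380000	3.878500	0.256500	12.176300	66.342100	1.034100
Cu	13.338000	7.167600	5.615800	1.673500	3.582800	0.247000	11.396600	64.812600	1.191000
Zn	14.074300	7.031800	5.165200	2.410000	3.265500	0.233300	10.316300	58.709700	1.304100
Se	17.000600	5.819600	3.973100	4.354300	2.409800	0.272600	15.237200	43.816300	2.840900
Br	17.178900	5.235800	5.637700	3.985100	2.172300	16.579600	0.260900	41.432800	2.955700
I	20.147200	18.994900	7.513800	2.273500	4.347000	0.381400	27.766000	66.877600	4.071200
Gd	25.070900	19.079800	13.851800	3.545450	2.253410	0.181951	12.933100	101.398000	2.419600
Pt	27.005900	17.763900	15.713100	5.783700	1.512930	8.811740	0.424593	38.610300	11.688300
Au	16.881900	18.591300	25.558200	5.860000	0.461100	8.621600	1.482600	36.395600	12.065800
Hg	20.680900	19.041700	21.657500	5.967600	0.545000	8.448400	1.572900	38.324600	12.608900
C	2.310000	1.020000	1.588600	0.865000	20.843900	10.207500	0.568700	51.651200	0.215600
N	12.212600	3.132200	2.012500	1.166300	0.005700	9.893300	28.997500	0.582600	-11.529000
O	3.048500	2.286800	1.546300	0.867000	13.277100	5.701100	0.323900	32.908900	0.250800
P	6.434500	4.179100	1.780000	1.490800	1.906700	27.157000	0.526000	68.164500	1.114900
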