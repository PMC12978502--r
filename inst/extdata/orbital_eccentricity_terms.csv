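# Trigonometric series for Earth's orbital eccentricity and fixed-frame
# longitude of perihelion (Berger-type secular solution).
#   e*sin(Pi) = sum_i M_i * sin(g_i * t + b_i)
#   e*cos(Pi) = sum_i M_i * cos(g_i * t + b_i)
# with t in years relative to 1950 CE, amplitude M dimensionless, rate g in
# arcseconds per year, phase b in degrees. e = sqrt(sin^2 + cos^2); Pi is the
# longitude of perihelion referred to the fixed ecliptic and equinox of 1950.
# Validated against the present-epoch eccentricity (~0.0167).
amplitude,rate_arcsec_yr,phase_deg
0.01860798,4.207205,28.620089
0.01627522,7.346091,193.788772
-0.01300660,17.857263,308.307024
0.00988829,17.220546,320.199637
-0.00336700,16.846733,279.376984
0.00333077,5.199079,87.195000
-0.00235400,18.231076,349.129677
0.00140015,26.216758,128.443387
0.00100700,6.359169,154.143880
0.00085700,16.210016,221.885250
0.00064990,3.065181,276.067785
0.00059900,16.583829,268.296071
0.00037800,18.493980,316.842643
-0.00033700,6.190953,319.374481
0.00027600,18.867793,282.081855
0.00018200,17.425567,179.108226
-0.00017400,6.186001,263.795988
-0.00012400,18.417441,345.312419
0.00001250,0.667863,39.247588
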