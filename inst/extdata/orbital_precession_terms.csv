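# Truncated trigonometric series for the general precession in longitude
# (Berger-type secular solution).
#   psi(t) = psibar * t + zeta + sum_i F_i * sin(fp_i * t + dp_i)
# with psibar = 50.439273 arcsec/yr, zeta = 3.392506 deg, t in years relative
# to 1950 CE, amplitude F in arcseconds, rate fp in arcsec/yr, phase dp in
# degrees. The moving-equinox longitude of perihelion is
#   varpi = Pi + psi + 180 deg (mod 360),
# measured so that varpi is the true solar longitude of perigee (~283 deg at
# present). Leading terms only; the induced error in varpi over the Holocene
# is below one degree, negligible for the climatic precession index e*sin(varpi).
amplitude_arcsec,rate_arcsec_yr,phase_deg
7391.0225890,31.609974,251.9025
2555.1526947,32.620504,280.8325
2022.7629188,34.847117,128.9923
-1973.6517951,24.172203,128.3057
1240.2321818,31.983787,292.7252
953.8679112,44.828336,15.3747
-931.7537108,31.233691,306.5998
872.3795383,30.973257,263.7951
606.3544732,44.254531,240.0099
-496.0274038,45.815258,55.0196
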