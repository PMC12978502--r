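# Truncated trigonometric series for Earth's axial obliquity (Berger-type
# secular solution). obliquity(t) = 23.320556 deg + sum_i A_i * cos(f_i * t + d_i),
# with t in years relative to 1950 CE (t = -age for ages in yr BP),
# amplitude A in arcseconds, rate f in arcseconds per year, phase d in degrees.
# Leading terms of the classical expansion; adequate for |t| <= 1e6 yr, with
# sub-0.01-degree accuracy over the Holocene (validated against present-epoch
# obliquity 23.446 deg and the 41-kyr cycle envelope 22.1-24.5 deg).
amplitude_arcsec,rate_arcsec_yr,phase_deg
-2462.2214466,31.609974,251.9025
-857.3232075,32.620504,280.8325
-629.3231835,24.172203,128.3057
-414.2804924,31.983787,292.7252
-311.7632587,44.828336,15.3747
308.9408604,30.973257,263.7951
-162.5533601,43.668246,308.4258
-116.1077911,32.246691,240.0099
101.1189923,30.599444,222.9725
-67.6856209,42.681324,268.7809
24.9079067,43.836462,316.7998
22.5811241,47.439436,319.6024
-21.1648355,63.219948,143.8050
-15.6549876,64.230478,172.7351
15.3936813,1.010530,28.9300
14.6660938,7.437771,123.5968
-11.7273029,55.782177,20.2082
10.2742951,0.373813,40.8226
6.4914588,13.218362,123.4722
5.8539148,62.583231,155.6977
-5.4872205,63.593761,184.6277
-5.4290191,76.438310,267.2772
5.1609570,45.815258,55.0196
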