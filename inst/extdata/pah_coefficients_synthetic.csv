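# SYNTHETIC predicted-adult-height coefficient table (generated 2026-10-01).
# Same functional form and layout as the published Khamis-Roche half-year
# coefficient tables (PAH = b0 + b1*stature + b2*weight + b3*midparent),
# but the values are a smooth internally calibrated stand-in, NOT a
# transcription of the published coefficients. Calibrated so that a child
# growing along the package's default synthetic growth curves (adult height
# 178 cm male / 164 cm female, midparent 170 cm) predicts its own adult
# height at every tabulated age. Suitable for pipeline testing and
# demonstration only; supply a transcription of the published table for
# real prediction.
sex,age_yr,b0,b1,b2,b3
male,4,57.9097,0.5,0.25,0.43
male,4.5,56.2411,0.51667,0.23889,0.41519
male,5,54.5769,0.53333,0.22778,0.40037
male,5.5,52.9241,0.55,0.21667,0.38556
male,6,51.2885,0.56667,0.20556,0.37074
male,6.5,49.6747,0.58333,0.19444,0.35593
male,7,48.0855,0.6,0.18333,0.34111
male,7.5,46.5217,0.61667,0.17222,0.3263
male,8,44.9817,0.63333,0.16111,0.31148
male,8.5,43.4604,0.65,0.15,0.29667
male,9,41.9473,0.66667,0.13889,0.28185
male,9.5,40.4248,0.68333,0.12778,0.26704
male,10,38.8644,0.7,0.11667,0.25222
male,10.5,37.2226,0.71667,0.10556,0.23741
male,11,35.4368,0.73333,0.09444,0.22259
male,11.5,33.4229,0.75,0.08333,0.20778
male,12,31.0821,0.76667,0.07222,0.19296
male,12.5,28.3264,0.78333,0.06111,0.17815
male,13,25.1311,0.8,0.05,0.16333
male,13.5,21.6033,0.81667,0.03889,0.14852
male,14,18.0126,0.83333,0.02778,0.1337
male,14.5,14.7214,0.85,0.01667,0.11889
male,15,12.0326,0.86667,0.00556,0.10407
male,15.5,10.0728,0.88333,-0.00556,0.08926
male,16,8.7949,0.9,-0.01667,0.07444
male,16.5,8.0583,0.91667,-0.02778,0.05963
male,17,7.7084,0.93333,-0.03889,0.04481
male,17.5,7.6171,0.95,-0.05,0.03
female,4,30.7524,0.5,0.25,0.43
female,4.5,30.0106,0.51667,0.23889,0.41519
female,5,29.2698,0.53333,0.22778,0.40037
female,5.5,28.5298,0.55,0.21667,0.38556
female,6,27.7881,0.56667,0.20556,0.37074
female,6.5,27.0398,0.58333,0.19444,0.35593
female,7,26.2754,0.6,0.18333,0.34111
female,7.5,25.4803,0.61667,0.17222,0.3263
female,8,24.6321,0.63333,0.16111,0.31148
female,8.5,23.6985,0.65,0.15,0.29667
female,9,22.636,0.66667,0.13889,0.28185
female,9.5,21.3906,0.68333,0.12778,0.26704
female,10,19.9052,0.7,0.11667,0.25222
female,10.5,18.1376,0.71667,0.10556,0.23741
female,11,16.0902,0.73333,0.09444,0.22259
female,11.5,13.8426,0.75,0.08333,0.20778
female,12,11.5593,0.76667,0.07222,0.19296
female,12.5,9.4506,0.78333,0.06111,0.17815
female,13,7.6979,0.8,0.05,0.16333
female,13.5,6.3935,0.81667,0.03889,0.14852
female,14,5.5331,0.83333,0.02778,0.1337
female,14.5,5.0496,0.85,0.01667,0.11889
female,15,4.8548,0.86667,0.00556,0.10407
female,15.5,4.8669,0.88333,-0.00556,0.08926
female,16,5.0214,0.9,-0.01667,0.07444
female,16.5,5.2723,0.91667,-0.02778,0.05963
female,17,5.5885,0.93333,-0.03889,0.04481
female,17.5,5.9494,0.95,-0.05,0.03
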