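 Synthetic single-subunit scattering profile (sphere R = 30 A), CRYSOL .int layout
 0.000000E+00  1.000000E+06  1.000000E+06  0.000000E+00
 1.000000E-02  9.821382E+05  9.821382E+05  0.000000E+00
 2.000000E-02  9.301827E+05  9.301827E+05  0.000000E+00
 3.000000E-02  8.488091E+05  8.488091E+05  0.000000E+00
 4.000000E-02  7.451340E+05  7.451340E+05  0.000000E+00
 5.000000E-02  6.278121E+05  6.278121E+05  0.000000E+00
 6.000000E-02  5.059800E+05  5.059800E+05  0.000000E+00
 7.000000E-02  3.882037E+05  3.882037E+05  0.000000E+00
 8.000000E-02  2.815832E+05  2.815832E+05  0.000000E+00
 9.000000E-02  1.911312E+05  1.911312E+05  0.000000E+00
 1.000000E-01  1.194929E+05  1.194929E+05  0.000000E+00
 1.100000E-01  6.701082E+04  6.701082E+04  0.000000E+00
 1.200000E-01  3.208710E+04  3.208710E+04  0.000000E+00
 1.300000E-01  1.175030E+04  1.175030E+04  0.000000E+00
 1.400000E-01  2.312216E+03  2.312216E+03  0.000000E+00
 1.500000E-01  9.083122E-01  9.083122E-01  0.000000E+00
 1.600000E-01  1.475773E+03  1.475773E+03  0.000000E+00
 1.700000E-01  4.164641E+03  4.164641E+03  0.000000E+00
 1.800000E-01  6.403250E+03  6.403250E+03  0.000000E+00
 1.900000E-01  7.395115E+03  7.395115E+03  0.000000E+00
 2.000000E-01  7.038365E+03  7.038365E+03  0.000000E+00
 2.100000E-01  5.681146E+03  5.681146E+03  0.000000E+00
 2.200000E-01  3.867858E+03  3.867858E+03  0.000000E+00
 2.300000E-01  2.126873E+03  2.126873E+03  0.000000E+00
 2.400000E-01  8.309596E+02  8.309596E+02  0.000000E+00
 2.500000E-01  1.396414E+02  1.396414E+02  0.000000E+00
 2.600000E-01  1.333725E+01  1.333725E+01  0.000000E+00
 2.700000E-01  2.759269E+02  2.759269E+02  0.000000E+00
 2.800000E-01  6.971814E+02  6.971814E+02  0.000000E+00
 2.900000E-01  1.068847E+03  1.068847E+03  0.000000E+00
 3.000000E-01  1.256102E+03  1.256102E+03  0.000000E+00
 3.100000E-01  1.216656E+03  1.216656E+03  0.000000E+00
 3.200000E-01  9.898906E+02  9.898906E+02  0.000000E+00
 3.300000E-01  6.657812E+02  6.657812E+02  0.000000E+00
 3.400000E-01  3.466066E+02  3.466066E+02  0.000000E+00
 3.500000E-01  1.136364E+02  1.136364E+02  0.000000E+00
 3.600000E-01  7.086780E+00  7.086780E+00  0.000000E+00
 3.700000E-01  2.227494E+01  2.227494E+01  0.000000E+00
 3.800000E-01  1.197912E+02  1.197912E+02  0.000000E+00
 3.900000E-01  2.439724E+02  2.439724E+02  0.000000E+00
 4.000000E-01  3.426883E+02  3.426883E+02  0.000000E+00
 4.100000E-01  3.823786E+02  3.823786E+02  0.000000E+00
 4.200000E-01  3.547700E+02  3.547700E+02  0.000000E+00
 4.300000E-01  2.747660E+02  2.747660E+02  0.000000E+00
 4.400000E-01  1.716921E+02  1.716921E+02  0.000000E+00
 4.500000E-01  7.766645E+01  7.766645E+01  0.000000E+00
 4.600000E-01  1.709058E+01  1.709058E+01  0.000000E+00
 4.700000E-01  2.588229E-01  2.588229E-01  0.000000E+00
 4.800000E-01  2.236460E+01  2.236460E+01  0.000000E+00
 4.900000E-01  6.734755E+01  6.734755E+01  0.000000E+00
 5.000000E-01  1.146443E+02  1.146443E+02  0.000000E+00
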