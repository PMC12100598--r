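# synthetic two-ellipsoid dimer, Debye intensity
# q I
5.00000000000000e-02 5.18175824589031e+07
5.35930114389439e-02 5.17649782452507e+07
5.74442175018955e-02 5.17046086709125e+07
6.15721721136054e-02 5.16353388019629e+07
6.59967624881016e-02 5.15558714661534e+07
7.07393049391619e-02 5.14647252277898e+07
7.58226475757489e-02 5.13602097516473e+07
8.12712803771625e-02 5.12403983747777e+07
8.71114531782178e-02 5.11030977400559e+07
9.33713021328651e-02 5.09458144056528e+07
1.00080985265515e-01 5.07657184364642e+07
1.07272827763110e-01 5.05596041182514e+07
1.14981477707924e-01 5.03238481286996e+07
1.23244073001349e-01 5.00543657662835e+07
1.32100420282867e-01 4.97465662025350e+07
1.41593186706180e-01 4.93953082102052e+07
1.51768105496417e-01 4.89948584607100e+07
1.62674196278726e-01 4.85388553146305e+07
1.74364001239736e-01 4.80202820870884e+07
1.86893838259624e-01 4.74314550943144e+07
2.00324072234323e-01 4.67640334119739e+07
2.14719405894998e-01 4.60090592189906e+07
2.30149191525878e-01 4.51570398526398e+07
2.46687765082201e-01 4.41980852005337e+07
2.64414804317959e-01 4.31221166575800e+07
2.83415712648770e-01 4.19191663066452e+07
3.03782030599239e-01 4.05797867757416e+07
3.25611876817013e-01 3.90955926513439e+07
3.49010420778203e-01 3.74599523048097e+07
3.74090389461538e-01 3.56688430006617e+07
4.00972610432224e-01 3.37218702057853e+07
4.29786593951947e-01 3.16234316751842e+07
4.60671156919430e-01 2.93839755152946e+07
4.93775091647490e-01 2.70212567344665e+07
5.29257882698591e-01 2.45614379239697e+07
5.67290475232336e-01 2.20398090444142e+07
6.08056098566611e-01 1.95008271005734e+07
6.51751148920000e-01 1.69971163967249e+07
6.98586135588289e-01 1.45870545381923e+07
7.48786695113416e-01 1.23306434087751e+07
8.02594678330846e-01 1.02835840160039e+07
8.60269315532411e-01 8.48989194914364e+06
9.22088465358020e-01 6.97402367676412e+06
9.88349953433012e-01 5.73426251162452e+06
1.05937300720030e+00 4.73981218588704e+06
1.13549979385989e+00 3.93424031052971e+06
1.21709706882503e+00 3.24702185657100e+06
1.30455794263690e+00 2.61245497926388e+06
1.39830377485009e+00 1.99124866466474e+06
1.49878620401318e+00 1.38596050261706e+06
1.60648932352420e+00 8.40112790755611e+05
1.72193201384347e+00 4.15741619811702e+05
1.84567044229994e+00 1.56352194682452e+05
1.97830074253403e+00 5.61683558056215e+04
2.12046188648595e+00 5.94114889895750e+04
2.27283876276572e+00 9.44772896534158e+04
2.43616547623557e+00 1.16168966228401e+05
2.61122888470106e+00 1.17755788469409e+05
2.79887238974970e+00 1.07491808347781e+05
3.00000000000000e+00 8.76856735998664e+04
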