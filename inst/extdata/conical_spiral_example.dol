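# dol pose file -- kind: conical_spiral_tubule
# subunits: 29
# R_max=14 R_min=10 p=6 n=3 V_h=8 N_spirals=1 L_dim=8 T_dim=5
# x y z alpha beta gamma
1.40000000000000e+01 0.00000000000000e+00 -8.86015259239031e+00 8.60814421226071e+01 0.00000000000000e+00 0.00000000000000e+00
1.16654903399266e+01 7.51860091676993e+00 -8.31344512757732e+00 8.60469534347349e+01 3.28024478887788e+01 0.00000000000000e+00
5.61847598568689e+00 1.25562304877279e+01 -7.76193349059569e+00 8.60115393357508e+01 6.58931461076768e+01 0.00000000000000e+00
-2.19829206138292e+00 1.34538854180689e+01 -7.20548898237777e+00 8.59751577298758e+01 9.92798166007518e+01 0.00000000000000e+00
-9.20702212809840e+00 9.88350883197668e+00 -6.64397705915004e+00 8.59377637928248e+01 1.32970531994416e+02 0.00000000000000e+00
-1.30372286458590e+01 3.01617622161251e+00 -6.07725695423758e+00 8.58993097402688e+01 1.66973738289163e+02 0.00000000000000e+00
-1.23492001266526e+01 -4.81432473831106e+00 -5.50518126783092e+00 8.58597445718342e+01 2.01298279473563e+02 0.00000000000000e+00
-7.34886466615372e+00 -1.08760584807772e+01 -4.92759552133586e+00 8.58190137875247e+01 2.35953424263267e+02 0.00000000000000e+00
2.15229447245905e-01 -1.29947032880140e+01 -4.34433767249822e+00 8.57770590729860e+01 2.70948895193525e+02 0.00000000000000e+00
7.61566671230326e+00 -1.03694081934238e+01 -3.75523758700158e+00 8.57338179494883e+01 3.06294900323323e+02 0.00000000000000e+00
1.21102608737124e+01 -3.93435571286430e+00 -3.16011646166782e+00 8.56892233838568e+01 3.42002167843349e+02 0.00000000000000e+00
1.19774398605491e+01 3.91066268638019e+00 -2.55878619373281e+00 8.56432033528194e+01 3.78081983919450e+02 0.00000000000000e+00
7.23006447792645e+00 1.01534972867635e+01 -1.95104868990845e+00 8.55956803553460e+01 4.14546234148911e+02 0.00000000000000e+00
-3.02805143427953e-01 1.23244012253441e+01 -1.33669510805666e+00 8.55465708654790e+01 4.51407449060018e+02 0.00000000000000e+00
-7.61824532906984e+00 9.51632006105422e+00 -7.15505023269158e-01 8.54957847168847e+01 4.88678854147269e+02 0.00000000000000e+00
-1.17113161267013e+01 2.83879966317284e+00 -8.72455089395761e-02 8.54432244088271e+01 5.26374425007044e+02 0.00000000000000e+00
-1.08361630986336e+01 -4.94036800472329e+00 5.48329878002178e-01 8.53887843214310e+01 5.64508948223549e+02 0.00000000000000e+00
-5.32383406996677e+00 -1.04929826983354e+01 1.19148222019204e+00 8.53323498258893e+01 6.03098088754941e+02 0.00000000000000e+00
2.44770449239603e+00 -1.13609484698825e+01 1.84248848574101e+00 8.52737962725891e+01 6.42158464687879e+02 0.00000000000000e+00
9.00639119205566e+00 -7.11084633772899e+00 2.50164291376216e+00 8.52129878368629e+01 6.81707730369148e+02 0.00000000000000e+00
1.13214256690962e+01 3.48802122956727e-01 3.16925855911338e+00 8.51497761980847e+01 7.21764669090221e+02 0.00000000000000e+00
8.26000032652970e+00 7.52902325251451e+00 3.84566901928835e+00 8.50839990229216e+01 7.62349296700719e+02 0.00000000000000e+00
1.25122184742687e+00 1.09529011278035e+01 4.53123037039430e+00 8.50154782174962e+01 8.03482977767077e+02 0.00000000000000e+00
-6.26385604858798e+00 8.88334830441158e+00 5.22632334399088e+00 8.49440179056874e+01 8.45188556182871e+02 0.00000000000000e+00
-1.04586728064953e+01 2.32045087243227e+00 5.93135578242928e+00 8.48694020814067e+01 8.87490502489175e+02 0.00000000000000e+00
-9.10157896305950e+00 -5.34308534162487e+00 6.64676541748138e+00 8.47913918708744e+01 9.30415080592301e+02 0.00000000000000e+00
-2.86624630687988e+00 -9.98956162102700e+00 7.37302302581141e+00 8.47097223260018e+01 9.73990537092103e+02 0.00000000000000e+00
4.84102941295387e+00 -9.01060580432672e+00 8.11063602564564e+00 8.46240986509817e+01 1.01824731708216e+03 0.00000000000000e+00
9.63362555999773e+00 -2.90520391836098e+00 8.86015259239031e+00 8.46240986509817e+01 1.06321831108684e+03 0.00000000000000e+00
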