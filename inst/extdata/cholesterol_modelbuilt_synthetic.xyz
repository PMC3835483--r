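74
model-built cholesterol (synthetic geometry; ETKDG+MMFF94)
C      4.482459    -0.913851     0.947561
C      5.712876    -0.290993     1.628321
C      6.806097     0.146494     0.657575
C      6.271666     1.105030    -0.420816
C      4.769062     1.002789    -0.601075
C      4.025284     2.112572    -0.743511
C      2.531913     2.119857    -0.796371
C      1.894877     0.837257    -0.230496
C      2.607473    -0.405450    -0.800608
C      4.163060    -0.395781    -0.488767
C      1.902704    -1.692438    -0.333395
C      0.437761    -1.698391    -0.743967
C     -0.382105    -0.514280    -0.176593
C      0.356426     0.844976    -0.403165
C     -0.198683     1.336632    -1.736062
C     -1.682355     1.042031    -1.571164
C     -1.720756    -0.391078    -1.030243
C     -0.587842    -0.679696     1.341373
C      4.828577    -1.325387    -1.540668
C     -3.060104    -0.840374    -0.376754
C     -3.082184    -2.378997    -0.259529
C     -4.335706    -0.438434    -1.166831
C     -4.873879     0.987404    -0.999129
C     -5.075861     1.517071     0.426187
C     -6.185926     0.891378     1.295347
C     -5.782009    -0.429778     1.945841
C     -7.515910     0.744104     0.558091
O      7.852258     0.792942     1.384403
H      4.608800    -2.004124     0.923203
H      3.638801    -0.727806     1.622794
H      5.394190     0.580739     2.217222
H      6.120151    -0.992067     2.367539
H      7.252784    -0.734198     0.183695
H      6.767259     0.882134    -1.374025
H      6.558518     2.135493    -0.173185
H      4.508741     3.085612    -0.806569
H      2.161267     2.980776    -0.226938
H      2.250300     2.277985    -1.843215
H      2.075798     0.837078     0.854656
H      2.492219    -0.355143    -1.894608
H      2.382157    -2.571488    -0.776319
H      1.970021    -1.817370     0.751335
H     -0.014301    -2.649000    -0.437736
H      0.408511    -1.690148    -1.841618
H     -0.014110     1.563588     0.346376
H     -0.035359     2.406430    -1.896100
H      0.224933     0.784121    -2.582095
H     -2.113810     1.743948    -0.848731
H     -2.209398     1.141777    -2.524688
H     -1.609977    -1.022409    -1.925047
H     -1.241604     0.103231     1.741129
H      0.360387    -0.603709     1.884500
H     -1.020410    -1.647379     1.603537
H      5.907772    -1.427755    -1.402850
H      4.420682    -2.340174    -1.500805
H      4.669595    -0.944707    -2.556812
H     -3.129994    -0.431461     0.633073
H     -3.981048    -2.715839     0.267993
H     -2.227425    -2.773509     0.290413
H     -3.081781    -2.847346    -1.250343
H     -4.159766    -0.615261    -2.236460
H     -5.155627    -1.117039    -0.902631
H     -5.821908     1.057098    -1.546999
H     -4.216318     1.686797    -1.523026
H     -5.326838     2.582387     0.320562
H     -4.126001     1.506258     0.972866
H     -6.354806     1.596632     2.121236
H     -5.722653    -1.245417     1.222826
H     -6.521040    -0.722108     2.700349
H     -4.815375    -0.340512     2.451650
H     -7.812730     1.691288     0.095863
H     -7.464320    -0.020418    -0.223650
H     -8.309768     0.450603     1.253620
H      8.154305     0.176804     2.073317
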