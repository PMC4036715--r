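# Gonnet-family amino-acid similarity matrix at 160 PAM,
# derived from the 1992 Gonnet-Cohen-Benner 250-PAM matrix by
# Markov-chain time rescaling. Units: 10*log10 odds.
   A      C      D      E      F      G      H      I      K      L      M      N      P      Q      R      S      T      V      W      Y
A   4.66   0.24  -1.12  -0.37  -3.75   0.17  -1.72  -1.77  -1.16  -2.20  -1.25  -1.15  -0.09  -0.73  -1.46   1.65   0.55   0.08  -5.50  -3.63
C   0.24  13.50  -5.39  -5.13  -1.82  -3.41  -2.25  -2.45  -4.87  -2.92  -1.86  -3.03  -5.27  -4.12  -3.56  -0.22  -1.28  -0.57  -2.06  -1.33
D  -1.12  -5.39   6.98   3.34  -6.85  -0.71  -0.13  -6.13  -0.18  -6.45  -4.92   2.68  -1.80   0.53  -1.52   0.14  -0.64  -4.88  -7.88  -4.34
E  -0.37  -5.13   3.34   5.89  -6.15  -2.03  -0.04  -4.42   1.27  -4.44  -3.17   0.41  -1.46   2.33  -0.35  -0.37  -0.81  -3.02  -6.32  -4.34
F  -3.75  -1.82  -6.85  -6.15   9.10  -7.65  -0.75   0.35  -5.36   1.83   1.48  -4.78  -5.86  -4.17  -5.19  -4.48  -3.62  -0.87   3.20   5.59
G   0.17  -3.41  -0.71  -2.03  -7.65   8.14  -2.68  -7.08  -2.36  -6.59  -5.30  -0.14  -3.05  -2.15  -2.11  -0.02  -2.38  -5.20  -5.51  -5.99
H  -1.72  -2.25  -0.13  -0.04  -0.75  -2.68   9.27  -3.77   0.34  -3.23  -2.14   1.47  -2.20   1.66   0.28  -0.82  -0.91  -3.58  -1.87   2.70
I  -1.77  -2.45  -6.13  -4.42   0.35  -7.08  -3.77   6.04  -3.40   3.10   2.96  -4.45  -4.37  -3.29  -3.98  -3.24  -1.23   4.01  -3.40  -1.99
K  -1.16  -4.87  -0.18   1.27  -5.36  -2.36   0.34  -3.40   5.48  -3.35  -2.13   0.69  -1.55   1.89   3.49  -0.39  -0.30  -2.90  -5.42  -3.40
L  -2.20  -2.92  -6.45  -4.44   1.83  -6.59  -3.23   3.10  -3.35   5.61   3.36  -4.80  -3.59  -2.40  -3.48  -3.53  -2.49   1.59  -1.89  -1.09
M  -1.25  -1.86  -4.92  -3.17   1.48  -5.30  -2.14   2.96  -2.13   3.36   7.66  -3.57  -4.12  -1.32  -2.87  -2.38  -1.06   1.45  -2.21  -1.30
N  -1.15  -3.03   2.68   0.41  -4.78  -0.14   1.47  -4.45   0.69  -4.80  -3.57   6.53  -2.12   0.53  -0.32   1.11   0.40  -3.73  -5.39  -2.11
P  -0.09  -5.27  -1.80  -1.46  -5.86  -3.05  -2.20  -4.37  -1.55  -3.59  -4.12  -2.12   9.58  -0.81  -2.04   0.04  -0.45  -3.10  -7.36  -4.76
Q  -0.73  -4.12   0.53   2.33  -4.17  -2.15   1.66  -3.29   1.89  -2.40  -1.32   0.53  -0.81   5.51   1.79  -0.06  -0.50  -2.61  -3.96  -2.85
R  -1.46  -3.56  -1.52  -0.35  -5.19  -2.11   0.28  -3.98   3.49  -3.48  -2.87  -0.32  -2.04   1.79   7.09  -0.96  -0.88  -3.44  -2.34  -2.89
S   1.65  -0.22   0.14  -0.37  -4.48  -0.02  -0.82  -3.24  -0.39  -3.53  -2.38   1.11   0.04  -0.06  -0.96   4.68   2.39  -1.94  -4.81  -2.90
T   0.55  -1.28  -0.64  -0.81  -3.62  -2.38  -0.91  -1.23  -0.30  -2.49  -1.06   0.40  -0.45  -0.50  -0.88   2.39   4.79  -0.16  -5.37  -3.19
V   0.08  -0.57  -4.88  -3.02  -0.87  -5.20  -3.58   4.01  -2.90   1.59   1.45  -3.73  -3.10  -2.61  -3.44  -1.94  -0.16   5.35  -4.53  -2.33
W  -5.50  -2.06  -7.88  -6.32   3.20  -5.51  -1.87  -3.40  -5.42  -1.89  -2.21  -5.39  -7.36  -3.96  -2.34  -4.81  -5.37  -4.53  15.86   3.80
Y  -3.63  -1.33  -4.34  -4.34   5.59  -5.99   2.70  -1.99  -3.40  -1.09  -1.30  -2.11  -4.76  -2.85  -2.89  -2.90  -3.19  -2.33   3.80  10.09
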