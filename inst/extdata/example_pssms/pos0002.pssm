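
Last position-specific scoring matrix computed
           A      C      D      E      F      G      H      I      K      L      M      N      P      Q      R      S      T      V      W      Y      A      C      D      E      F      G      H      I      K      L      M      N      P      Q      R      S      T      V      W      Y
    1 T     16     -4      1      0     11     -2      6     12     -1      7      6     14      9      0     -1     11     10      1     -7     10   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
    2 T      9     -1      0     -1     16      2      8     17      3     15     -3     13     15      3      3     15     21      5     -3     19   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
    3 Y      8      7      1     -8     14     -3     13     13     -7     14      4     10     13      3     -1     10     12      2      0     10   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
    4 C      4      2      0     -1      1     -1     -3      2     -2     -5     -1      5     -1     -2      1      2     -5      3      0      3   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
    5 H    -14      3     -2      0    -11      0    -10    -10      0    -11      4    -16     -9     -3      1    -10    -12     -2     -1    -14   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
    6 P    -20      1      0     -5     -7      0    -10    -11      0    -14     -3    -13    -13     -2      1    -17    -22      1      3    -14   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
    7 M     -9     -3      5      2    -13      1    -10    -13      1     -5      0    -12    -14     -4      1     -6    -11      3     -3    -13   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
    8 S      5     -2      0     -2     -3      5     -1     -4      2     -2      1      0      0     -5      0     -1      2     -4     -8     -4   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
    9 D     16      0     -4      4      9     -1      5     12     -5     15      0      9      9      1     -2     12      8      3      2     13   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   10 H     17     -9     -3      1     15     -2     13     16      0     14      2     18     16      0      0     13     11     -4      0     20   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   11 S     13     -3     -3     -2     12      2      9      8      2      8     -1      7      6      2     -3      7     14     -1      0      8   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   12 M      2      2     -3      1      1      1      2      0      4     -3      4      3      5      0      0     -2     -3      8     -1     -3   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   13 R    -11     -1     -4      1    -11      1     -9    -10      0    -11      1     -6     -7      1     -1    -14     -8      2     -5    -14   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   14 Y    -25     -1     -8      3    -18      2    -15    -14      5    -15      2    -20    -18     -1      0    -13    -14      0     -3    -16   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   15 A     -8      3      2      0     -7     -4    -10     -8     -1    -12     -4    -14    -13     -3     -3    -15     -8      3      2     -9   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   16 V     -1     -2      2     -6      3      3     -1      3      0      3     -2      2     -3      2     -1     -3      3     -1      0      2   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   17 N     14      2     -1     -4      8      1     11      3      0     11      3      8     10      2     -3     11     14      2     -4     12   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   18 F     13     -4     -2     -3     17      3     16     20     -2     15      2     13     13     -5     -1     10     19     -1      2     17   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   19 I      6     -4     -2      1     12     -2     12     12      2      9      0      9     11      3      2      9     11     -7      2      9   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   20 Y      4     -5      1     -1      3     -6      5     -2     -4     -4      0     -1     -6     -5      1     -1      1      1      0     -1   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   21 L    -10      0      1     -2    -10     -1    -14    -14      0    -16      2     -8    -10      0      3     -7    -13     -2      0     -9   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   22 V     -5     -1      1     -3    -18     -3    -11    -12     -2    -14     -1    -17    -15     -1      1    -16    -19     -2      4    -16   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   23 T     -8      4      0      0     -8      7     -9    -10     -2    -11      0    -10    -15      0      0    -12    -12      0      1    -13   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   24 T      3      0      2     -3     -2     -1     -5      3      3      4     -5      2      1      3      3     -2      0      4      4     -4   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   25 A     13      4      1     -1     12     -1     10     10      3     11      5      6     11     -4      4     12      8      1      0     19   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   26 Q     13      6      2     -3     20      3     13     14      5     17      2     13     14     -1     -4     14     17      3      4     10   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   27 K      9     -1      1     -4      6      2      8     17     -1     11      2     13     11      8      3      9      8      2      0     11   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   28 W      3      1      5      3      5      2     -5     -6      0     -2     -6     -1      1     -4      2     -1      1      0      3      6   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   29 T     -7     -3     -3     -4     -7      8    -12     -9     -5    -10      0    -18    -10     -2      3     -7     -8      2     -1     -8   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   30 C    -13      2      5      0    -17      0    -16    -14     -1    -14     -1    -18    -16      0     -3    -10    -19      0     -3    -16   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   31 N    -14     -3     -1     -2    -11      6    -12     -9      5    -13     -4     -8     -7      1      7    -13     -8     -4      3     -9   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0
   32 D      5     -3      0     -3     -2      1     -6      2     -1      0      2     -1      0     -2     -8      0     -6      1      7      5   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0   0

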