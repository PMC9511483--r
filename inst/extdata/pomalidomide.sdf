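pomalidomide
     RDKit          2D

 31 33  0  0  0  0  0  0  0  0999 V2000
    3.9424   -2.2202    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    3.4983   -0.7875    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.5171    0.3135    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.0731    1.7462    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.6102    2.0781    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.5915    0.9771    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.0355   -0.4556    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8101   -1.3207    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.7896   -2.8205    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.3913   -0.4226    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8241   -0.8666    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0126    0.6215    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.3956    1.2023    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.5901    0.2950    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.9731    0.8758    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -4.4016   -1.1931    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0186   -1.7739    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.8301   -3.2620    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.0916    0.9976    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7735    2.2230    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    5.4052   -2.5521    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.9236   -3.3212    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.9800   -0.0184    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.0919    2.8472    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.1662    3.5108    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1380   -2.2005    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6808    2.0844    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8208    0.8580    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.4965    2.2211    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5834    2.4635    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
   -5.5961   -2.1004    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  2  0
  3  4  1  0
  4  5  2  0
  5  6  1  0
  6  7  2  0
  7  8  1  0
  8  9  2  0
  8 10  1  0
 10 11  1  0
 11 12  1  0
 12 13  1  0
 13 14  1  0
 14 15  2  0
 14 16  1  0
 16 17  1  0
 17 18  2  0
 10 19  1  0
 19 20  2  0
  7  2  1  0
 17 11  1  0
 19  6  1  0
  1 21  1  0
  1 22  1  0
  3 23  1  0
  4 24  1  0
  5 25  1  0
 11 26  1  0
 12 27  1  0
 12 28  1  0
 13 29  1  0
 13 30  1  0
 16 31  1  0
M  END
$$$$
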