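HSYN0003
HSYN0035
HSYN0108
HSYN0114
HSYN0145
HSYN0205
HSYN0216
HSYN0223
HSYN0381
HSYN0399
HSYN0473
HSYN0528
HSYN0621
HSYN0624
HSYN0662
HSYN0693
HSYN0711
HSYN0779
HSYN0827
HSYN0859
HSYN0913
HSYN0916
HSYN0973
HSYN0982
HSYN1000
HSYN1081
HSYN1106
HSYN1112
HSYN1172
HSYN1320
HSYN1339
HSYN1346
HSYN1403
HSYN1423
HSYN1437
HSYN1440
HSYN1520
HSYN1594
HSYN1725
HSYN1762
HSYN6001
HSYN6002
HSYN6003
HSYN6004
HSYN6005
HSYN6006
HSYN6007
HSYN6008
HSYN6009
HSYN6010
HSYN6011
HSYN6012
HSYN6013
HSYN6014
HSYN6015
HSYN6016
HSYN6017
HSYN6018
HSYN6019
HSYN6020
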