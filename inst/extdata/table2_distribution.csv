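state,host,mll,individuals,samples
Benin,sorghum,A,3,2
Benin,sugarcane,A,6,1
Benin,pearl millet,A,1,1
Cameroon,sorghum,A,20,5
Kenya,sorghum,A,2,1
Kenya,sugarcane,A,2,4
Kenya,sugarcane,C,4,4
Niger,sorghum,A,5,2
Australia,sugarcane,B,11,7
Brazil,sugarcane,C,2,1
Columbia,sugarcane,C,7,3
Ecuador,sugarcane,C,1,1
Guadeloupe,sugarcane,C,6,5
Martinique,sugarcane,C,3,3
Mauritius,sugarcane,C,1,1
Reunion,sorghum,C,3,3
Reunion,sugarcane,C,7,5
Hawaii,sugarcane,D,3,3
Louisiana,sorghum,D,1,1
Louisiana,sugarcane,D,8,7
China,sorghum,E,2,1
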