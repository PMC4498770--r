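(t19:0.1177954389,((((t15:0.1824717925,(t14:0.04318312686,t17:0.04812854659):0.03626433507):0.02041777984,(t12:0.01394173248,t10:0.03157340753):0.3241271086):0.2880406432,t6:0.1291020402):0.2390750876,(((t2:0.02626591042,(t13:0.0436231649,(t5:0.2023995148,t8:0.008566212931):0.008361320803):0.01291024768):0.1089889696,(((t11:0.01401798074,t20:0.05005323581):0.02409390034,(t3:0.1067782704,t4:0.1058720847):0.08342569833):0.007919340156,((t7:0.03302451102,t9:0.1184394221):0.1151147145,(t16:0.1794515127,t1:0.1833983458):0.2136301331):0.05759195937):0.0563430252):0.02607014207,t18:0.03468551054):0.2407522028):0.03012398983);
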