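id,formula,n_deuterium,adducts,polarity,expected_rt,primary_adduct,primary_n_down,products_mz
IS_Car_4:0-d7,C11H21NO4,7,[M+H]+,pos,0.3,[M+H]+,0,239.1983
IS_LPC_14:0-d42,C19H42NO4P,42,[M+H]+,pos,0.4,[M+H]+,0,422.5560;421.5498;420.5435
IS_Car_16:0-d3,C23H45NO4,3,[M+H]+,pos,0.5,[M+H]+,0,403.3610
IS_FA_17:0-d33,C17H34O2,33,[M-H]-,neg,1.1,[M-H]-,0,302.4557;301.4495;300.4432
IS_PS_28:0-d54,C34H66NO10P,54,[M-H]-,neg,1.4,[M-H]-,0,732.7741;731.7678;730.7615;729.7553;728.7490
IS_PI_34:1-d31,C43H81O13P,31,[M-H]-,neg,2.9,[M-H]-,0,864.7162;865.7225;866.7288
IS_SM_34:1-d31,C39H79N2O6P,31,[M+H]+;[M+Na]+;[M+K]+,pos,3.0,[M+Na]+,0,733.7632;734.7670;755.7451;756.7514;771.7190;772.7253
IS_PG_34:1-d31,C40H77O10P,31,[M-H]-,neg,3.0,[M-H]-,0,775.6939;776.7002;777.7065;778.7127
IS_PA_34:1-d31,C37H71O8P,31,[M-H]-,neg,3.4,[M-H]-,0,700.6509;701.6571;702.6634;703.6697;704.6760
IS_Cer_16:0-d31,C34H67NO3,31,[M+H]+;[M+H-H2O]+;[M+Na]+;[M+K]+,pos,3.9,[M+H]+,0,548.6851;549.6914;550.6977;551.7039;566.6951;567.7014;568.7076;569.7139;590.6896;591.6959;606.6636;607.6698
IS_PC_34:1-d31,C42H82NO8P,31,[M+H]+;[M+Na]+;[M+K]+,pos,3.9,[M+Na]+,0,790.7700;791.7750;812.7553;813.7616;828.7292;829.7355
IS_PE_34:1-d31,C39H76NO8P,31,[M+H]+;[M+Na]+;[M+K]+,pos,4.0,[M+H]+,0,747.7181;748.7254;749.7327;769.7021;770.7084;771.7146;785.6760;786.6823;787.6886
IS_TG_45:0-d87,C48H92O6,87,[M+H]+;[M+NH4]+;[M+Na]+;[M+K]+,pos,5.8,[M+H]+,0,850.2239;851.2301;852.2364;853.2427;867.2504;868.2567;869.2630;870.2693;872.2059;873.2121;874.2184;875.2247;888.1798;889.1861;890.1923;891.1986
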