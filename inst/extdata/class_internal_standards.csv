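class_code,analyte_class,n_species,adducts,ionisation_mode,internal_standard
Carn,Acyl-carnitines,48,[M+H]+,pos,IS_Car_4:0-d7;IS_Car_16:0-d3
Cer,Ceramides,85,[M+H]+;[M+H-H2O]+,pos,IS_Cer_16:0-d31
CL,Cardiolipins,56,[M-H]-,neg,IS_TG_45:0-d87
DG,Diacylglycerols,6,[M+H-H2O]+;[M+Na]+;[M+K]+,pos,IS_TG_45:0-d87
GM1,Gangliosides (GM1),24,[M-H]-,neg,IS_PG_34:1-d31
Hex-Cer,Hexosylceramides,56,[M+H]+;[M+H-H2O]+,pos,IS_Cer_16:0-d31
LPC,Lyso-phosphatidylcholines,23,[M+H]+,pos,IS_LPC_14:0-d42
LPE,Lyso-phosphatidylethanolamines,19,[M+H]+,pos,IS_LPC_14:0-d42
LPI,Lyso-phosphatidylinositols,19,[M-H]-,neg,IS_PI_34:1-d31
LPS,Lyso-phosphoserines,20,[M-H]-,neg,IS_PS_28:0-d54
Lyso_CL,Lyso-cardiolipins,23,[M-H]-,neg,IS_TG_45:0-d87
MG,Monoacylglycerols,1,[M+H-H2O]+;[M+Na]+;[M+K]+,pos,IS_TG_45:0-d87
PA,Phosphatidic acids,26,[M-H]-,neg,IS_PA_34:1-d31
PC,Phosphatidylcholines,43,[M+H]+,pos,IS_PC_34:1-d31
PE,Phosphatidylethanolamines,19,[M+H]+,pos,IS_PE_34:1-d31
PG,Phosphatidylglycerol,34,[M-H]-,neg,IS_PG_34:1-d31
PI,Phosphatidylinositols,21,[M-H]-,neg,IS_PI_34:1-d31
PS,Phosphatidylserines,36,[M-H]-,neg,IS_PS_28:0-d54
S,Sulfatides,72,[M-H]-,neg,IS_PG_34:1-d31
SM,Sphingomyelins,54,[M+H]+;[M+Na]+;[M+K]+,pos,IS_SM_34:1-d31
TG,Triacylglycerides,89,[M+H]+;[M+NH4]+;[M+Na]+;[M+K]+,pos,IS_TG_45:0-d87
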