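id,mode,sex,extra_chromosomes,biparental_disomies,outcome
HM01,dispermic_CHM,XX,,,SR
HM02,dispermic_CHM,XX,,,SR
HM03,dispermic_CHM,XY,22:maternal,,SR
HM04,dispermic_CHM,XY,,,GTN
HM05,dispermic_CHM,XYY,,,GTN
HM06,dispermic_CHM,XY,,,GTN
HM07,dispermic_CHM,XX,,,SR
HM08,dispermic_CHM,XY,,,SR
HM09,dispermic_CHM,XX,,,SR
HM10,dispermic_CHM,XX,7:maternal;11:maternal,4,SR
HM11,dispermic_CHM,XY,13:maternal,6,SR
HM12,dispermic_CHM,XX,,,SR
HM13,dispermic_CHM,XY,6:maternal,,SR
HM14,dispermic_CHM,XX,,,SR
HM15,dispermic_CHM,XX,14:paternal,,GTN
HM16,dispermic_CHM,XY,,,GTN
HM17,dispermic_CHM,XY,3:paternal,,SR
HM18,dispermic_CHM,XY,,,SR
HM19,dispermic_CHM,XX,,,GTN
HM20,dispermic_CHM,XX,,,SR
HM21,dispermic_CHM,XY,7:maternal,,SR
HM22,dispermic_CHM,XX,,,GTN
HM23,dispermic_CHM,XY,,,SR
HM24,dispermic_CHM,XY,15:maternal,2,SR
HM25,dispermic_CHM,XY,,,SR
HM26,dispermic_CHM,XY,,,SR
HM27,dispermic_CHM,XY,,,SR
HM28,dispermic_CHM,XY,,,SR
HM29,dispermic_CHM,XY,,,SR
HM30,dispermic_CHM,XY,,,SR
HM31,dispermic_CHM,XY,,,SR
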