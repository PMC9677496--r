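class,prefix,weight
MI,I21,1
MI,I22,1
MI,I252,1
CHF,I099,1
CHF,I110,1
CHF,I130,1
CHF,I132,1
CHF,I255,1
CHF,I420,1
CHF,I425,1
CHF,I426,1
CHF,I427,1
CHF,I428,1
CHF,I429,1
CHF,I43,1
CHF,I50,1
CHF,P290,1
PVD,I70,1
PVD,I71,1
PVD,I731,1
PVD,I738,1
PVD,I739,1
PVD,I771,1
PVD,I790,1
PVD,I792,1
PVD,K551,1
PVD,K558,1
PVD,K559,1
PVD,Z958,1
PVD,Z959,1
Stroke,G45,1
Stroke,G46,1
Stroke,H340,1
Stroke,I60,1
Stroke,I61,1
Stroke,I62,1
Stroke,I63,1
Stroke,I64,1
Stroke,I65,1
Stroke,I66,1
Stroke,I67,1
Stroke,I68,1
Stroke,I69,1
Dementia,F00,1
Dementia,F01,1
Dementia,F02,1
Dementia,F03,1
Dementia,F051,1
Dementia,G30,1
Dementia,G311,1
Pulmonary,I278,1
Pulmonary,I279,1
Pulmonary,J40,1
Pulmonary,J41,1
Pulmonary,J42,1
Pulmonary,J43,1
Pulmonary,J44,1
Pulmonary,J45,1
Pulmonary,J46,1
Pulmonary,J47,1
Pulmonary,J60,1
Pulmonary,J61,1
Pulmonary,J62,1
Pulmonary,J63,1
Pulmonary,J64,1
Pulmonary,J65,1
Pulmonary,J66,1
Pulmonary,J67,1
Pulmonary,J684,1
Pulmonary,J701,1
Pulmonary,J703,1
Rheumatic,M05,1
Rheumatic,M06,1
Rheumatic,M315,1
Rheumatic,M32,1
Rheumatic,M33,1
Rheumatic,M34,1
Rheumatic,M351,1
Rheumatic,M353,1
Rheumatic,M360,1
PUD,K25,1
PUD,K26,1
PUD,K27,1
PUD,K28,1
LiverMild,B18,1
LiverMild,K700,1
LiverMild,K701,1
LiverMild,K702,1
LiverMild,K703,1
LiverMild,K709,1
LiverMild,K713,1
LiverMild,K714,1
LiverMild,K715,1
LiverMild,K717,1
LiverMild,K73,1
LiverMild,K74,1
LiverMild,K760,1
LiverMild,K762,1
LiverMild,K763,1
LiverMild,K764,1
LiverMild,K768,1
LiverMild,K769,1
LiverMild,Z944,1
DM,E100,1
DM,E110,1
DM,E120,1
DM,E130,1
DM,E140,1
DM,E101,1
DM,E111,1
DM,E121,1
DM,E131,1
DM,E141,1
DM,E106,1
DM,E116,1
DM,E126,1
DM,E136,1
DM,E146,1
DM,E108,1
DM,E118,1
DM,E128,1
DM,E138,1
DM,E148,1
DM,E109,1
DM,E119,1
DM,E129,1
DM,E139,1
DM,E149,1
DMcx,E102,2
DMcx,E112,2
DMcx,E122,2
DMcx,E132,2
DMcx,E142,2
DMcx,E103,2
DMcx,E113,2
DMcx,E123,2
DMcx,E133,2
DMcx,E143,2
DMcx,E104,2
DMcx,E114,2
DMcx,E124,2
DMcx,E134,2
DMcx,E144,2
DMcx,E105,2
DMcx,E115,2
DMcx,E125,2
DMcx,E135,2
DMcx,E145,2
DMcx,E107,2
DMcx,E117,2
DMcx,E127,2
DMcx,E137,2
DMcx,E147,2
Paralysis,G041,2
Paralysis,G114,2
Paralysis,G801,2
Paralysis,G802,2
Paralysis,G81,2
Paralysis,G82,2
Paralysis,G830,2
Paralysis,G831,2
Paralysis,G832,2
Paralysis,G833,2
Paralysis,G834,2
Paralysis,G839,2
Renal,I120,2
Renal,I131,2
Renal,N032,2
Renal,N033,2
Renal,N034,2
Renal,N035,2
Renal,N036,2
Renal,N037,2
Renal,N052,2
Renal,N053,2
Renal,N054,2
Renal,N055,2
Renal,N056,2
Renal,N057,2
Renal,N18,2
Renal,N19,2
Renal,N250,2
Renal,Z490,2
Renal,Z491,2
Renal,Z492,2
Renal,Z940,2
Renal,Z992,2
Cancer,C00,2
Cancer,C01,2
Cancer,C02,2
Cancer,C03,2
Cancer,C04,2
Cancer,C05,2
Cancer,C06,2
Cancer,C07,2
Cancer,C08,2
Cancer,C09,2
Cancer,C10,2
Cancer,C11,2
Cancer,C12,2
Cancer,C13,2
Cancer,C14,2
Cancer,C15,2
Cancer,C16,2
Cancer,C17,2
Cancer,C18,2
Cancer,C19,2
Cancer,C20,2
Cancer,C21,2
Cancer,C22,2
Cancer,C23,2
Cancer,C24,2
Cancer,C25,2
Cancer,C26,2
Cancer,C30,2
Cancer,C31,2
Cancer,C32,2
Cancer,C33,2
Cancer,C34,2
Cancer,C37,2
Cancer,C38,2
Cancer,C39,2
Cancer,C40,2
Cancer,C41,2
Cancer,C43,2
Cancer,C45,2
Cancer,C46,2
Cancer,C47,2
Cancer,C48,2
Cancer,C49,2
Cancer,C50,2
Cancer,C51,2
Cancer,C52,2
Cancer,C53,2
Cancer,C54,2
Cancer,C55,2
Cancer,C56,2
Cancer,C57,2
Cancer,C58,2
Cancer,C60,2
Cancer,C61,2
Cancer,C62,2
Cancer,C63,2
Cancer,C64,2
Cancer,C65,2
Cancer,C66,2
Cancer,C67,2
Cancer,C68,2
Cancer,C69,2
Cancer,C70,2
Cancer,C71,2
Cancer,C72,2
Cancer,C73,2
Cancer,C74,2
Cancer,C75,2
Cancer,C76,2
Cancer,C81,2
Cancer,C82,2
Cancer,C83,2
Cancer,C84,2
Cancer,C85,2
Cancer,C88,2
Cancer,C90,2
Cancer,C91,2
Cancer,C92,2
Cancer,C93,2
Cancer,C94,2
Cancer,C95,2
Cancer,C96,2
Cancer,C97,2
LiverSevere,I850,3
LiverSevere,I859,3
LiverSevere,I864,3
LiverSevere,I982,3
LiverSevere,K704,3
LiverSevere,K711,3
LiverSevere,K721,3
LiverSevere,K729,3
LiverSevere,K765,3
LiverSevere,K766,3
LiverSevere,K767,3
Mets,C77,6
Mets,C78,6
Mets,C79,6
Mets,C80,6
HIV,B20,6
HIV,B21,6
HIV,B22,6
HIV,B24,6
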