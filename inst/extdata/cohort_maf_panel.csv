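locus,rsid,maf_caucasian,maf_mexican,replication_panel
IQCJ-SCHIP1,rs12497650,0.32,0.27,FALSE
IQCJ-SCHIP1,rs4501157,0.35,0.24,FALSE
IQCJ-SCHIP1,rs13091349,0.17,0.09,FALSE
IQCJ-SCHIP1,rs2044704,0.26,0.41,FALSE
IQCJ-SCHIP1,rs1962071,0.27,0.38,FALSE
IQCJ-SCHIP1,rs7634829,0.44,0.28,FALSE
IQCJ-SCHIP1,rs2621294,0.38,0.23,FALSE
IQCJ-SCHIP1,rs6800211,0.29,0.14,FALSE
IQCJ-SCHIP1,rs17782879,0.30,0.39,FALSE
IQCJ-SCHIP1,rs1868414,0.33,0.17,FALSE
IQCJ-SCHIP1,rs2595260,0.25,0.52,FALSE
IQCJ-SCHIP1,rs6763890,0.34,0.20,FALSE
NXPH1,rs6956210,0.24,0.13,FALSE
NXPH1,rs2107779,0.55,0.41,FALSE
NXPH1,rs10273195,0.20,0.24,FALSE
NXPH1,rs12216689,0.28,0.32,FALSE
NXPH1,rs6963644,0.08,0.04,FALSE
NXPH1,rs17150341,0.30,0.16,FALSE
NXPH1,rs1013868,0.33,0.45,FALSE
NXPH1,rs4318981,0.36,0.36,FALSE
NXPH1,rs17153997,0.43,0.30,FALSE
NXPH1,rs7801099,0.45,0.53,FALSE
NXPH1,rs4725120,0.46,0.47,FALSE
NXPH1,rs10238726,0.31,0.38,FALSE
NXPH1,rs1012960,0.50,0.46,FALSE
NXPH1,rs11767429,0.30,0.34,FALSE
NXPH1,rs4333500,0.40,0.45,FALSE
NXPH1,rs7793115,0.10,0.05,FALSE
NXPH1,rs7799856,0.43,0.39,FALSE
NXPH1,rs7806226,0.16,0.41,FALSE
NXPH1,rs13221144,0.23,0.11,FALSE
NXPH1,rs17406479,0.19,0.31,FALSE
NXPH1,rs10486228,0.18,0.44,FALSE
NXPH1,rs17154569,0.18,0.08,FALSE
NXPH1,rs4141002,0.12,0.17,FALSE
NXPH1,rs7805772,0.19,0.40,FALSE
NXPH1,rs2349780,0.38,0.49,FALSE
NXPH1,rs2107474,0.42,0.49,FALSE
NXPH1,rs11769942,0.37,0.43,FALSE
NXPH1,rs6952383,0.10,0.05,FALSE
NXPH1,rs6974252,0.14,0.23,FALSE
NXPH1,rs10265408,0.28,0.31,FALSE
NXPH1,rs2189904,0.33,0.18,FALSE
NXPH1,rs2057862,0.41,0.53,FALSE
PHF17,rs2217023,0.19,0.74,FALSE
PHF17,rs4975270,0.43,0.47,FALSE
PHF17,rs11722830,0.21,0.18,FALSE
PHF17,rs12505447,0.19,0.16,FALSE
PHF17,rs6534704,0.08,0.03,FALSE
PHF17,rs13148510,0.04,0.01,FALSE
PHF17,rs13143771,0.28,0.32,FALSE
PHF17,rs13142964,0.07,0.05,FALSE
MYB,rs9321493,0.45,0.45,FALSE
MYB,rs11154794,0.13,0.10,FALSE
MYB,rs210798,0.42,0.43,FALSE
MYB,rs210936,0.48,0.30,FALSE
MYB,rs7757388,0.16,0.05,FALSE
MYB,rs17639758,0.03,0.02,FALSE
MYB,rs1013891,0.35,0.23,FALSE
MYB,rs2179308,0.51,0.43,FALSE
IQCJ-SCHIP1,rs1449009,0.29,0.60,TRUE
IQCJ-SCHIP1,rs61332355,0.18,0.33,TRUE
IQCJ-SCHIP1,rs12485627,0.40,0.32,FALSE
IQCJ-SCHIP1,rs2595242,0.52,0.26,FALSE
IQCJ-SCHIP1,rs7639937,0.25,0.49,FALSE
IQCJ-SCHIP1,rs9820807,0.16,0.07,FALSE
IQCJ-SCHIP1,rs1375409,0.29,0.38,FALSE
IQCJ-SCHIP1,rs1967363,0.22,0.36,FALSE
IQCJ-SCHIP1,rs9824310,0.40,0.46,FALSE
IQCJ-SCHIP1,rs11915303,0.27,0.33,FALSE
IQCJ-SCHIP1,rs9835214,0.46,0.39,FALSE
IQCJ-SCHIP1,rs11921343,0.19,0.26,FALSE
IQCJ-SCHIP1,rs13066560,0.16,0.08,FALSE
IQCJ-SCHIP1,rs1675497,0.29,0.32,FALSE
IQCJ-SCHIP1,rs9839862,0.11,0.17,FALSE
IQCJ-SCHIP1,rs16829875,0.22,0.37,FALSE
IQCJ-SCHIP1,rs17795566,0.36,0.23,FALSE
IQCJ-SCHIP1,rs9860588,0.23,0.10,FALSE
IQCJ-SCHIP1,rs16830408,0.27,0.23,FALSE
IQCJ-SCHIP1,rs17798579,0.17,0.16,FALSE
IQCJ-SCHIP1,rs2364930,0.40,0.23,FALSE
IQCJ-SCHIP1,rs9865997,0.14,0.29,FALSE
IQCJ-SCHIP1,rs2595241,0.26,0.58,FALSE
IQCJ-SCHIP1,rs7632574,0.19,0.29,FALSE
IQCJ-SCHIP1,rs2621308,0.2589,0.5895,FALSE
SLIT2,rs2952724,0.3511,0.4789,FALSE
PHF17,rs1216352,0.3475,0.5921,TRUE
PHF17,rs1216365,0.6196,0.3421,TRUE
MYB,rs6920829,0.1241,0.1032,TRUE
NXPH1,rs6463808,0.1773,0.4,TRUE
NELL1,rs752088,0.3841,0.4579,TRUE
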