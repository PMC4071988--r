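snp_id,study_id,model,or,ci_low,ci_high,p
rs861539,Auranen,homozygote,0.99,0.83,1.18,0.88
rs861539,Auranen,heterozygote,0.99,0.88,1.12,0.89
rs861539,Auranen,dominant,0.99,0.88,1.11,0.87
rs861539,Auranen,recessive,0.99,0.84,1.17,0.91
rs861539,Beesley,homozygote,0.93,0.67,1.27,0.63
rs861539,Beesley,heterozygote,0.96,0.77,1.19,0.69
rs861539,Beesley,dominant,0.95,0.77,1.17,0.62
rs861539,Beesley,recessive,0.95,0.71,1.27,0.72
rs861539,Quaye,homozygote,0.89,0.72,1.11,0.31
rs861539,Quaye,heterozygote,0.92,0.79,1.07,0.27
rs861539,Quaye,dominant,0.91,0.79,1.05,0.21
rs861539,Quaye,recessive,0.93,0.76,1.14,0.51
rs861539,Webb,homozygote,0.97,0.74,1.28,0.83
rs861539,Webb,heterozygote,0.91,0.75,1.10,0.32
rs861539,Webb,dominant,0.92,0.77,1.10,0.37
rs861539,Webb,recessive,1.02,0.79,1.32,0.87
rs861539,Total,homozygote,0.95,0.85,1.06,0.37
rs861539,Total,heterozygote,0.95,0.88,1.03,0.22
rs861539,Total,dominant,0.95,0.88,1.02,0.19
rs861539,Total,recessive,0.97,0.88,1.08,0.63
rs1799794,Auranen,homozygote,0.72,0.52,1.00,0.048
rs1799794,Auranen,heterozygote,1.11,0.98,1.26,0.087
rs1799794,Auranen,dominant,1.07,0.95,1.20,0.29
rs1799794,Auranen,recessive,0.69,0.50,0.96,0.027
rs1799794,Quaye,homozygote,0.67,0.45,0.99,0.04
rs1799794,Quaye,heterozygote,1.09,0.94,1.25,0.25
rs1799794,Quaye,dominant,1.04,0.91,1.19,0.57
rs1799794,Quaye,recessive,0.65,0.44,0.96,0.027
rs1799794,Total,homozygote,0.70,0.54,0.90,0.005
rs1799794,Total,heterozygote,1.10,1.00,1.21,0.04
rs1799794,Total,dominant,1.06,0.96,1.15,0.24
rs1799794,Total,recessive,0.67,0.52,0.87,0.002
rs1799796,Auranen,homozygote,1.07,0.89,1.29,0.47
rs1799796,Auranen,heterozygote,0.89,0.79,1.01,0.062
rs1799796,Auranen,dominant,0.93,0.83,1.04,0.188
rs1799796,Auranen,recessive,1.13,0.95,1.35,0.17
rs1799796,Quaye,homozygote,1.08,0.87,1.33,0.5
rs1799796,Quaye,heterozygote,0.93,0.81,1.07,0.31
rs1799796,Quaye,dominant,0.96,0.84,1.09,0.536
rs1799796,Quaye,recessive,1.11,0.91,1.37,0.30
rs1799796,Total,homozygote,1.07,0.93,1.24,0.33
rs1799796,Total,heterozygote,0.91,0.83,0.99,0.04
rs1799796,Total,dominant,0.94,0.86,1.03,0.16
rs1799796,Total,recessive,1.13,0.98,1.29,0.08
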