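gene	abundance
gene01	180.11
gene02	46.52
gene03	65.72
gene04	75.62
gene05	18.2
gene06	24.76
gene07	45.53
gene08	166.09
gene09	123.07
gene10	305.87
gene11	96.66
gene12	18.51
gene13	46.91
gene14	115.05
gene15	20.46
gene16	60.2
gene17	38.87
gene18	63.87
gene19	24.16
gene20	45.19
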