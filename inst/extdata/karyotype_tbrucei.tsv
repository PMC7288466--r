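# Karyotype: Trypanosoma brucei (procyclic)
# Nuclear chromosome sizes (bp) as published; source assemblies from
# TriTrypDB (trypanosomatids) and NCBI (yeasts).
chromosome	length_bp
I	1064672
II	1193948
III	1653225
IV	1590432
V	1802303
VI	1618915
VII	2205233
VIII	2481190
IX	3542885
X	4144375
XI	5223313
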