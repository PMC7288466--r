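# Karyotype: Schizosaccharomyces pombe (mitotic cells)
# Nuclear chromosome sizes (bp) as published; source assemblies from
# TriTrypDB (trypanosomatids) and NCBI (yeasts).
chromosome	length_bp
I	5598923
II	4397795
III	2465919
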