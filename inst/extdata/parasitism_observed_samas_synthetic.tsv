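# Synthetic stand-in for the digitized parasitism-ratio series of Samas et
# al. (a short, highly variable series). Only the final-year value (47.7%) is
# reported in the text this package reproduces; the earlier rows are
# plausible placeholders, NOT field data. Columns: year, ratio.
year	ratio
0	0.32
1	0.41
2	0.52
3	0.477
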