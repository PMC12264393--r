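# Synthetic stand-in for the digitized reed-warbler parasitism-ratio series
# of Brooke et al. (observation years 0, 1, 10, 11, 12). Only the final-year
# value (5.7%) is taken from the published field study; the earlier
# rows are plausible interpolations, NOT field data. Columns: year, ratio.
year	ratio
0	0.085
1	0.078
10	0.064
11	0.061
12	0.057
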