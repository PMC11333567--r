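#kmer	level_mean	level_stdv
AA	108.297977	1.778571
AC	80.425827	1.777715
AG	84.445660	2.068945
AT	86.701656	2.770537
CA	82.234613	2.247114
CC	82.421760	2.685878
CG	95.985115	2.757696
CT	89.064358	2.185356
GA	91.221261	2.699214
GC	107.519825	2.072915
GG	92.855890	2.639552
GT	111.734014	2.155163
TA	108.251615	2.856327
TC	92.592164	1.979302
TG	105.168537	1.623854
TT	93.741444	2.724434
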