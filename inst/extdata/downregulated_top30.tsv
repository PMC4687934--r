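id	expression_change	orientation	conv_mRNA_RT	conv_ncRNA_RT	tandem_RT
NPL3	-6.17	.	.	.	.
YRO2	-4.22	C	Y	.	Y
THO1	-3.44	C	Y	.	.
HXT1	-3.34	T	.	.	Y
PTC7	-3.12	C	Y	.	.
YJR015W	-2.92	C	.	.	.
CYC1	-2.80	C	Y	.	Y
YPR172W	-2.79	C	Y	.	.
TPO2	-2.70	C	Y	.	.
HSP30	-2.51	C	.	.	Y
FMP48	-2.42	C	.	.	.
TPO1	-2.36	T	.	Y	Y
STP4	-2.22	T	.	.	Y
UNG1	-2.20	C	Y	.	.
PTC2	-2.18	T	.	Y	.
ADE17	-2.18	C	Y	.	.
ISF1	-2.16	T	.	.	Y
HXT4	-2.16	T	.	Y	.
FMP12	-2.15	T	.	Y	.
EFM3	-2.11	T	.	Y	.
FMP41	-2.09	T	.	.	Y
GSY1	-2.09	T	.	.	Y
SIA1	-2.08	C	Y	.	.
TPO4	-2.07	C	.	.	.
SCS7	-2.06	T	.	Y	Y
MIG3	-2.04	T	.	Y	.
WSC4	-2.02	T	.	Y	.
PTI1	-1.94	T	.	Y	.
HOR2	-1.92	T	.	.	Y
IML3	-1.90	C	Y	.	Y
POA1	-1.89	C	Y	.	Y
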