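name	chrom	leftMarker	leftBp	rightMarker	rightBp
3.05	3	bnlg1505	147812359	dupssr23	166846373
4.10	4	umc1101	241805620	umc1109	243738469
10.03	10	bnlg1451	4436646	umc2016	62064437
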