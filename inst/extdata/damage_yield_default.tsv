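energy_mev	ssb_per_alpha	dsb_per_alpha
1	72.933909757663	80.53729490710530570
2	107.323543856389	43.59815046945480788
3	88.834782011462	13.27582809534627906
4	58.098648823046	3.19411192086092344
5	33.395778846622	0.67543131484242824
6	17.691293461796	0.13162995115355194
7	8.858469290665	0.02424707387132180
8	4.256455487065	0.00428602071514698
9	1.981794683471	0.00073412556285679
10	0.900075951447	0.00012265813701292
11	0.400654520016	0.00002008596819384
12	0.175409328706	0.00000323504948778
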