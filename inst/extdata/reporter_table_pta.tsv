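isotype	family	species	span_start	span_end	sequence	terminal_met	printed_mh
TUA1	TUA	Pta	414	451	EEGEFSEAREDLAALEKDYEEVGAESPDGEDGDEGDEY	FALSE	4180.691
TUA2	TUA	Pta	414	450	EEGEFSEAREDLAALEKDYEEVGAEGVDDEEDNEDYE	FALSE	4224.717
TUA3	TUA	Pta	414	451	EEGEFSEAREDLAALEKDYEEVGAESAEGDDEDGEEYM	TRUE	4194.707
TUA4	TUA	Pta	414	450	EEGEFSEAREDLAALEKDYEEVGAEGVDDEEEGDDYQ	FALSE	4166.712
TUA5	TUA	Pta	414	451	EEGEFSEAREDLAALEKDYEEVGAESAEGDDDDGDEYM	TRUE	4166.675
TUA6	TUA	Pta	414	449	EEGEFSEAREDLAALEKDYEEVGAEGGDEEGEEEDY	FALSE	4024.637
TUA7	TUA	Pta	414	451	EEGEFSEAREDLAALEKDYEEVGAESAEGEDDEGEEYM	TRUE	4208.722
TUA8	TUA	Pta	414	449	EEGEFSEAREDLAALEKDYEEVGAEGGDDEGEDEDY	FALSE	3996.606
TUB1	TUB	Pta	416	449	NDLVSEYQQYQDATADEEGEYEDEEEGEYQGDYQ	FALSE	4038.559
TUB2	TUB	Pta	416	450	NDLVSEYQQYQDATADEEGEYEEEEEGDEYQQDYQ	FALSE	4238.63
TUB3	TUB	Pta	416	447	NDLVSEYQQYQDATADEEGEFEDEEEAYGDEA	FALSE	3688.4
TUB4	TUB	Pta	416	446	NDLVSEYQQYQDATADEEGEYEDEEAYQDED	FALSE	3690.4
TUB5	TUB	Pta	416	444	NDLVSEYQQYQDATADEDYEDEEEELHDM	TRUE	3475.373
TUB6	TUB	Pta	416	443	NDLVSEYQQYQDATTYEDCEDEEELHDM	TRUE	3364.32
TUB7	TUB	Pta	416	445	NDLVAEYQQYQDATADDEEYEEEEEEEIGA	FALSE	3524.414
TUB8	TUB	Pta	416	445	NDLVAEYQQYQDATIDEEEYEEEEEEEHDT	FALSE	3692.5
TUB9	TUB	Pta	416	442	NDLVSEYQQYQDAAADNEGEYDEEEPM	TRUE	3104.24
TUB10	TUB	Pta	416	442	NDLVSEYQQYQDAAADNDDEYDEEEAM	TRUE	3122.214
TUB11	TUB	Pta	416	444	NDLVAEYQQYQDATAEEEIEYEEDDGVEN	FALSE	3408.403
TUB12	TUB	Pta	416	444	NDLVAEYQQYQDATTEEDIEYEEEDGVEN	FALSE	3438.414
TUB13	TUB	Pta	411	442	NDLVSEYQQYQDATAEDDIDYEDEEEEEAAEM	TRUE	3738.473
TUB14	TUB	Pta	416	446	NDLVSEYQQYQDATADEEVDYEDEEEEEAEM	TRUE	3667.436
TUB15	TUB	Pta	416	445	NDLVSEYQQYQDATVDEELEYEDEEEEEAA	FALSE	3582.456
TUB16	TUB	Pta	416	446	NDLVSEYQQYQDATAEEEVDYEDEEEDAAGM	TRUE	3537.41
TUB17	TUB	Pta	416	448	NDLVSEYQQYQDATADEEGEYEDEEDGQYAEQM	TRUE	3843.506
TUB18	TUB	Pta	416	448	NDLVSEYQQYQDATADEEGEYDDEEEEEGQYAE	FALSE	3890.496
TUB19	TUB	Pta	419	449	NDLVAEYQQYQDATIEEDGEYEEEGEENYDA	FALSE	3658.462
TUB20	TUB	Pta	419	449	NDLVAEYQQYQDATVEEDGEYEVEGEENYDD	FALSE	3658.462
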