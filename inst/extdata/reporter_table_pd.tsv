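isotype	family	species	span_start	span_end	sequence	terminal_met	printed_mh
TUA1	TUA	Pd	414	451	EEGEFSEAREDLAALEKDYEEVGAESPDGEDGDEGDEY	FALSE	4180.691
TUA2	TUA	Pd	414	450	EEGEFSEAREDLAALEKDYEEVGAEGVDDEEDNEDYE	FALSE	4224.717
TUA3	TUA	Pd	414	451	EEGEFSEAREDLAALEKDYEEVGAETAEGDDEEGEEYM	TRUE	4222.738
TUA4	TUA	Pd	414	450	EEGEFSEAREDLAALEKDYEEVGAEGVDDEEEGDDYQ	FALSE	4166.712
TUA5	TUA	Pd	414	451	EEGEFSEAREDLAALEKDYEEVGAESAEGDDDDGDEYM	TRUE	4166.675
TUA6	TUA	Pd	414	449	EEGEFSEAREDLAALEKDYEEVGAEGGDEEGEEEDY	FALSE	4024.637
TUA7	TUA	Pd	414	451	EEGEFSEAREDLAALEKDYEEVGAESAEGEDDDGEEYM	TRUE	4194.707
TUA8	TUA	Pd	414	449	EEGEFSEAREDLAALEKDYEEVGAEGGDDEGEDEDY	FALSE	3996.606
TUB1	TUB	Pd	416	449	NDLVSEYQQYQDATADEEGEYEDEEEGEYQGDYQ	FALSE	4038.559
TUB2	TUB	Pd	416	450	NDLVSEYQQYQDATADEEGEYEEEEEGEEYQQDYQ	FALSE	4252.655
TUB3	TUB	Pd	416	447	NDLVSEYQQYQDATADEEGEFEDEEEAYGDEA	FALSE	3688.4
TUB4	TUB	Pd	416	446	NDLVSEYQQYQDATADEEGEYEDEEAYQDED	FALSE	3690.4
TUB5	TUB	Pd	416	444	NDLVSEYQQYQDATADEDYEDEEEELHDM	TRUE	3475.373
TUB6	TUB	Pd	416	443	NDLVSEYQQYQDATTYEDCEDEEELHDM	TRUE	3364.32
TUB7	TUB	Pd	416	445	NDLVAEYQQYQDATADDEEYEEEEEEEIGA	FALSE	3524.414
TUB8	TUB	Pd	416	445	NDLVAEYQQYQDATIDEEEYEEEEEEEHDT	FALSE	3692.5
TUB9	TUB	Pd	416	442	NDLVSEYQQYQDAVADNEGEYDEEEPM	TRUE	3132.271
TUB10	TUB	Pd	416	444	NDLVSEYQQYQDAAADNDDEYDEEEIVEN	FALSE	3423.378
TUB11	TUB	Pd	416	444	NDLVAEYQQYQDATAEEEIEYEEDDGVEN	FALSE	3408.403
TUB12	TUB	Pd	416	444	NDLVAEYQQYQDATTEEDIEYEEEDGVEN	FALSE	3438.414
TUB13	TUB	Pd	411	442	NDLVSEYQQYQDATAEDDIDYEDEEEEEAAEM	TRUE	3738.473
TUB14	TUB	Pd	416	446	NDLVSEYQQYQDATADEEVDYEDEEEEEAEM	TRUE	3667.436
TUB15	TUB	Pd	416	445	NDLVSEYQQYQDATVDEELEYEDEEEEEAA	FALSE	3582.456
TUB16	TUB	Pd	416	446	NDLVSEYQQYQDATADEEVDYEDEEEDAAGM	TRUE	3523.39
TUB17	TUB	Pd	416	448	NDLVSEYQQYQDATADEEGEYEDEEDGQYAEQM	TRUE	3843.506
TUB18	TUB	Pd	416	450	NDLVSEYQQYQDATADEEGEYDDEEEEEGQYAEQM	TRUE	4101.591
TUB19	TUB	Pd	419	449	NDLVAEYQQYQDATIEEDGEYEEEGEENYDA	FALSE	3658.462
TUB20	TUB	Pd	419	449	NDLVAEYQQYQDATVEEDGEYEEEGEENYDD	FALSE	3688.4
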