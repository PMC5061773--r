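>TUA1 species=Pd family=TUA span=414-451 terminal_met=0 printed_mh=4180.691
EEGEFSEAREDLAALEKDYEEVGAESPDGEDGDEGDEY
>TUA2 species=Pd family=TUA span=414-450 terminal_met=0 printed_mh=4224.717
EEGEFSEAREDLAALEKDYEEVGAEGVDDEEDNEDYE
>TUA3 species=Pd family=TUA span=414-451 terminal_met=1 printed_mh=4222.738
EEGEFSEAREDLAALEKDYEEVGAETAEGDDEEGEEYM
>TUA4 species=Pd family=TUA span=414-450 terminal_met=0 printed_mh=4166.712
EEGEFSEAREDLAALEKDYEEVGAEGVDDEEEGDDYQ
>TUA5 species=Pd family=TUA span=414-451 terminal_met=1 printed_mh=4166.675
EEGEFSEAREDLAALEKDYEEVGAESAEGDDDDGDEYM
>TUA6 species=Pd family=TUA span=414-449 terminal_met=0 printed_mh=4024.637
EEGEFSEAREDLAALEKDYEEVGAEGGDEEGEEEDY
>TUA7 species=Pd family=TUA span=414-451 terminal_met=1 printed_mh=4194.707
EEGEFSEAREDLAALEKDYEEVGAESAEGEDDDGEEYM
>TUA8 species=Pd family=TUA span=414-449 terminal_met=0 printed_mh=3996.606
EEGEFSEAREDLAALEKDYEEVGAEGGDDEGEDEDY
>TUB1 species=Pd family=TUB span=416-449 terminal_met=0 printed_mh=4038.559
NDLVSEYQQYQDATADEEGEYEDEEEGEYQGDYQ
>TUB2 species=Pd family=TUB span=416-450 terminal_met=0 printed_mh=4252.655
NDLVSEYQQYQDATADEEGEYEEEEEGEEYQQDYQ
>TUB3 species=Pd family=TUB span=416-447 terminal_met=0 printed_mh=3688.400
NDLVSEYQQYQDATADEEGEFEDEEEAYGDEA
>TUB4 species=Pd family=TUB span=416-446 terminal_met=0 printed_mh=3690.400
NDLVSEYQQYQDATADEEGEYEDEEAYQDED
>TUB5 species=Pd family=TUB span=416-444 terminal_met=1 printed_mh=3475.373
NDLVSEYQQYQDATADEDYEDEEEELHDM
>TUB6 species=Pd family=TUB span=416-443 terminal_met=1 printed_mh=3364.320
NDLVSEYQQYQDATTYEDCEDEEELHDM
>TUB7 species=Pd family=TUB span=416-445 terminal_met=0 printed_mh=3524.414
NDLVAEYQQYQDATADDEEYEEEEEEEIGA
>TUB8 species=Pd family=TUB span=416-445 terminal_met=0 printed_mh=3692.500
NDLVAEYQQYQDATIDEEEYEEEEEEEHDT
>TUB9 species=Pd family=TUB span=416-442 terminal_met=1 printed_mh=3132.271
NDLVSEYQQYQDAVADNEGEYDEEEPM
>TUB10 species=Pd family=TUB span=416-444 terminal_met=0 printed_mh=3423.378
NDLVSEYQQYQDAAADNDDEYDEEEIVEN
>TUB11 species=Pd family=TUB span=416-444 terminal_met=0 printed_mh=3408.403
NDLVAEYQQYQDATAEEEIEYEEDDGVEN
>TUB12 species=Pd family=TUB span=416-444 terminal_met=0 printed_mh=3438.414
NDLVAEYQQYQDATTEEDIEYEEEDGVEN
>TUB13 species=Pd family=TUB span=411-442 terminal_met=1 printed_mh=3738.473
NDLVSEYQQYQDATAEDDIDYEDEEEEEAAEM
>TUB14 species=Pd family=TUB span=416-446 terminal_met=1 printed_mh=3667.436
NDLVSEYQQYQDATADEEVDYEDEEEEEAEM
>TUB15 species=Pd family=TUB span=416-445 terminal_met=0 printed_mh=3582.456
NDLVSEYQQYQDATVDEELEYEDEEEEEAA
>TUB16 species=Pd family=TUB span=416-446 terminal_met=1 printed_mh=3523.390
NDLVSEYQQYQDATADEEVDYEDEEEDAAGM
>TUB17 species=Pd family=TUB span=416-448 terminal_met=1 printed_mh=3843.506
NDLVSEYQQYQDATADEEGEYEDEEDGQYAEQM
>TUB18 species=Pd family=TUB span=416-450 terminal_met=1 printed_mh=4101.591
NDLVSEYQQYQDATADEEGEYDDEEEEEGQYAEQM
>TUB19 species=Pd family=TUB span=419-449 terminal_met=0 printed_mh=3658.462
NDLVAEYQQYQDATIEEDGEYEEEGEENYDA
>TUB20 species=Pd family=TUB span=419-449 terminal_met=0 printed_mh=3688.400
NDLVAEYQQYQDATVEEDGEYEEEGEENYDD
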