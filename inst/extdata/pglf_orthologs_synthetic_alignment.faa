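>PglF
YVFLVPNYCFCELLMIVWWAHVMLVGISFTVNHCEHIVNEANVCMQYANYLSMTYWCAFL
YWSCFWDQFWYGWWNLETTVYARMHWLMPGQVSTKDMNPQLGWTFYPGQFLMTCCEWGNL
RDNGQCYLTFEHTNSWPVHFAMARLNWSVKPDTLAVAWQAPCKWDVEPNNDQYIIAPPIP
ICLFDHCKKLYWLAVGHWNPLIGLLPWDGCMCDSPNLHPGWAYPAGYMKYEGHHVYEISF
MVVAQLSPQEFPQYATQFSAPTAQQCCAKDMAKIKAIHFRTQSCGMVAGQPTHDIKFAYP
KMMPDVQWICPWTREVSVRICNTLDSGERVVQSCYWLWPTWRGMLSREPHFRFVCHFVIM
ASYHILLDCPHPAQLSIEAERMVHEHSYFYHFQQWDEISKNVAYQGVEQCVGPDVGFCQR
NGKEKWHVYVYTWHEHAVYMMVPDSWTICLFYQTHTSHGQHASMKFELFFFQTLDHMDIW
FYSTLMESKCIHWKSFTPLKYTHISMHGEFSKNQRNTRFARAAKWIGAIVFWCGLRKGGV
SMLIPNSTMFKSTVPVSQCVLGCNKWPYIEIKYERMPAYIEGGFSHIIQM
>Ma467
------------------------------------------------------------
------------------------------------------------------------
------------------------------------------------------------
------------------------------------------------------------
------------------------------------------------------------
------------TDEVSSRICETLDSGFHTVQSCYWHCPTLRGMLSLTPHFRFACGFVMK
ISYVILLDQPFPWQLSIEAELMHHDHSTFAFFEQKDEISKNVAYQGVEFCVGPDEPFFGI
NGKEKWHVYVYQWHEHLVYMMSPHQWTICLNYQTHTSDTQHAVMKFCLFEWQTMPHMSIW
WYSTLMESKCRQWKSFTMLKYTHILMHCTFSMNQWNTRFARAAKWIGAIVGWCGWRKGGV
SMLIMNSTMFKSVVPDSQCVSGWTKWPYIEIYYERNPAYIEQVNSHIIPN
>Cotonvirus_ORF_718
------------------------------------------------------------
------------------------------------------------------------
------------------------------------------------------------
------------------------------------------------------------
------------------------------------------------------------
------------TREVSPRICNMANSGIRVVFSIRWLYNTWRGMCSREPKTRFVFTFSIM
ASYHCTLICPMQAYLSLKAERHVRENSYFYYWAQKDEIIKNFAYWGVEQCPHVDVGFDQR
NGKLKWHTYVYTWYEHAVYMMMPDSWTPCLFPQMHTSRGQRAIMSNAAFNGLTKPHMDHK
FYSTWMNFIKIELHEFTPSKYTHIFMHGEFGKNQRNTRFAKDAKWIIAIVAWCGLSKGGV
SMLIPLSTMFKSTVPASQCVTGCNKWPYNTIKYYFMPAYHEGRYSWIIQM
>Tupanvirus_L515
------------------------------------------------------------
------------------------------------------------------------
------------------------------------------------------------
------------------------------------------------------------
------------------------------------------------------------
------------TREVVVRCCNTIHSWERWSKSCMWLWLTWYGCLSREPHFRFVCKFWIM
PSYCILYDQPIPGQLTIEAERMQHQHSYEYHFQRFDEISWNVAYQGVEQCMGPDMHFCQR
NGKEPWHVYVTTWHEHAVYMMWSSHWTVCLFYQSHLSHGQHASMKFEGMKFHTLDHMDHV
FFSTCMESKCIHWKSFTTLKPTHIWMAFEHSKNCRNTRKAVGAKVIGAIVFWCGGREGGV
WMLIPNSTMFKSDVPQSQCVLGCNKWPGQWIKYTRMFAVINGGQSPCIQM
>Moumouvirus_gp464
------------------------------------------------------------
------------------------------------------------------------
------------------------------------------------------------
------------------------------------------------------------
------------------------------------------------------------
------------THETSGRICNTLMSGKRVIQSCYWLWPTWTGMLSRKPHFRAWWGFVRE
WSYHILLACWHFAQLSPEAERNVHEPIYWYHSQRWNEISKNVAYQGVEQGVGPDIPEVQP
INKKKRVVLVRTWENHAIKMMEPDSWACCLFAQTSTWHGQHSSMKNMLFFFQFLDHMDNW
KYKTLNESKCIKWFDWTGLKYTHISMHGTFSKNQQNPRFASAAKWAGAIVEWCCLRDGGT
SMCISNKMMCKSTVPVSQCHLGYWKWNFFPIKWERDPGYIVYGDYHHIQM
>Monve_mvR525
------------------------------------------------------------
------------------------------------------------------------
------------------------------------------------------------
------------------------------------------------------------
------------------------------------------------------------
------------TREVSVTECNTLDSGQRVVQEHVVLWVTWRGMLSIEPHFRFHCHFVIM
AKYWILLLCPFPAQLSIQAERMPPEHSRFYHFQQWNSISQNVAGRGVEQCVGPDLGFGRR
NTHESWHVYVYTWHGHAVYMMVPVSWTQCLFYQTSTSHGQHASMEFELIFFQTLDHMDIF
GMSTFMESKRIHWKMFTPLKYTHISMEGFFVKCRRNTVFVGAAKMIHPIVFMCGLRFGYV
DVNIPNSTMFKSKVPVSQCVFRCIKWDRSEISYERQLAYISGTFSYIIQM
>Mm419
------------------------------------------------------------
------------------------------------------------------------
------------------------------------------------------------
------------------------------------------------------------
------------------------------------------------------------
------------ARYWSVRIDNWADSGERVLQSVMWWDPSWRGMLSREPGFNFRCHFAHI
YSKPGVLFCPIPEQLHITAERMGVEASPFYHFPQWNEIRKNVAYQGVEQGVGPDVGCWGR
QGKEQWHVYVRTWQAHVVYSMVSDSWDMCLFGQTHTSDPQHARMKFVLFLDGVLDKMDIW
FYSCLMEYWCDCWKSETPRKYTRISMHYEYSKNQPNTRFARACFWIGAIVFLEGLHKGGV
SWPIYNSTMFKSTVPVSGPFLGCNKWPYCEIITEPMPAYIEFGDSHIWQM
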