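family	pollen_type	value
Amaranthaceae	Alternanthera brasiliana	0.62
Amaranthaceae	Amaranthus type	0.75
Apocynaceae	Mandevilla type	5.49
Arecaceae	Syagrus romanzoffiana	7.62
Asteraceae	Baccharis type	3.87
Asteraceae	Lepidaploa type	9.49
Asteraceae	Tridax type	8.36
Brassicaceae	Artemisia type	3.50
Celastraceae	Maytenus ilicifolia	1.12
Commelinaceae	Commelina benghalensis	2.75
Fabaceae	Cenostigma pluviosum	6.62
Fabaceae	Delonix regia	0.12
Fabaceae	Mimosa type	0.12
Fabaceae	Myroxylon peruiferum	1.37
Lamiaceae	Hyptis type	0.20
Malpighiaceae	Banisteriopsis type	0.50
Malpighiaceae	Malpighia emarginata	1.00
Malvaceae	Eriotheca type	0.25
Myrtaceae	Eucalyptus type	7.62
Solanaceae	Solanum type	24.97
Vochysiaceae	Vochysia type	0.12
NI	Sp 1	6.49
NI	Sp 2	2.75
NI	Sp 3	3.00
NI	Sp 4	0.62
NI	Sp 5	0.50
NI	Sp 6	0.25
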