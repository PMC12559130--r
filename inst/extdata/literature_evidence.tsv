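mirna_id	disease	biofluid	citation
hsa-miR-106b-3p	PD	blood	Xie 2022
hsa-miR-128-3p	PD	blood	Ravanidis 2020
hsa-miR-128-3p	PD	blood	Braunger 2024
hsa-miR-193a-3p	PD	blood	Dong 2016
hsa-miR-199a-5p	PD	blood	Martins 2011
hsa-miR-199a-5p	PD	blood	Li 2024
hsa-miR-410-3p	PD	blood	Ravanidis 2020
hsa-miR-487b-3p	PD	blood	Kern 2021
hsa-miR-505-3p	PD	blood	Khoo 2012
hsa-miR-505-3p	PD	blood	Yao 2018
hsa-miR-193b-5p	PD	blood	Baghi 2021
hsa-miR-103a-3p	PD	blood	Schwienbacher 2017
hsa-miR-103a-3p	PD	blood	Serafin 2015
hsa-miR-103a-3p	PD	blood	Soto 2023
hsa-miR-454-5p	PD	blood	Cardo 2013
hsa-miR-654-5p	PD	blood	Cai 2021
hsa-miR-654-5p	PD	blood	Hou 2023
hsa-miR-671-5p	PD	blood	Uwatoko 2019
hsa-miR-671-5p	PD	blood	Khoo 2012
hsa-miR-542-5p	PD	csf	Mo 2016
hsa-miR-516a-6p	PD	brain	Hoss 2016
hsa-miR-516a-6p	PD	brain	Chatterjee 2017
hsa-miR-95-3p	PD	csf	dos Santos 2018
hsa-miR-95-3p	PD	brain	Briggs 2015
hsa-miR-374a-5p	PD	blood	Martins 2011
hsa-miR-374a-5p	PD	blood	Tong 2022
hsa-miR-374a-5p	PD	csf	Tong 2022
hsa-miR-374a-5p	PD	brain	Briggs 2015
hsa-miR-93-5p	MSA	blood	Pérez-Soriano 2020
hsa-miR-92a-1-5p	MSA	blood	Kume 2017
hsa-miR-29c-3p	MSA	blood	Vallelunga 2014
hsa-miR-130a-3p	MSA	blood	Kume 2017
hsa-miR-1203	MSA	brain	Wakabayashi 2016
hsa-miR-1909-5p	MSA	brain	Wakabayashi 2016
hsa-miR-24-1-5p	MSA	blood	Vallelunga 2014
hsa-miR-24-1-5p	MSA	blood	Kume 2017
hsa-miR-24-1-5p	MSA	csf	Marques 2017
hsa-miR-425-5p	PSP	blood	Manna 2021
hsa-miR-425-5p	PSP	blood	Ramaswamy 2022
hsa-miR-99b-5p	PSP	blood	Ramaswamy 2022
hsa-miR-423-5p	PSP	csf	Nonaka 2022
hsa-miR-132-3p	PSP	brain	Smith 2011
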