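term	concept_id
heart	C0018787
copd	C5000001
chronic obstructive pulmonary disease	C5000001
emphysema	C5000002
chronic bronchitis	C5000003
bronchitis	C5000004
asthma	C5000005
dyspnea	C5000006
shortness of breath	C5000006
wheezing	C5000007
wheeze	C5000007
cough	C5000008
sputum	C5000009
hypoxia	C5000010
hypoxemia	C5000010
bronchodilator	C5000011
albuterol	C5000012
tiotropium	C5000013
prednisone	C5000014
spirometry	C5000015
fev1	C5000016
oxygen	C5000017
supplemental oxygen	C5000017
exacerbation	C5000018
copd exacerbation	C5000018
tobacco	C5000019
smoking	C5000019
smoker	C5000019
pack years	C5000020
inhaler	C5000021
nebulizer	C5000022
pulmonary	C5000023
lung	C5000024
lungs	C5000024
airway obstruction	C5000025
breath sounds	C5000026
rhonchi	C5000027
crackles	C5000028
pneumonia	C5000029
respiratory failure	C5000030
pulmonary function test	C5000015
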