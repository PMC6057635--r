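study_id,study_name,population_id,population_name,dce_id,dce_name,education,income_possessions_benefits,tobacco,alcohol,pregnancy_childbirth_puerperium
AOBF,All Our Babies and All Our Families (AOB/F),mothers,Mothers,24w_gestation,24 weeks gestation,4,8,5,14,0
AOBF,All Our Babies and All Our Families (AOB/F),mothers,Mothers,36w_gestation,36 weeks gestation,0,3,7,9,0
AOBF,All Our Babies and All Our Families (AOB/F),mothers,Mothers,4m_postpartum,4 months postpartum,0,6,5,4,0
AOBF,All Our Babies and All Our Families (AOB/F),mothers,Mothers,1y_postpartum,1 year postpartum,0,8,5,4,0
AOBF,All Our Babies and All Our Families (AOB/F),mothers,Mothers,3y_postpartum,3 years postpartum,1,2,5,4,0
AOBF,All Our Babies and All Our Families (AOB/F),children,Children,1y_postpartum,1 year postpartum,0,2,0,0,0
APrON,Alberta Pregnancy Outcomes and Nutrition (APrON),mothers,Mothers,trimester1,First trimester,1,1,15,15,49
APrON,Alberta Pregnancy Outcomes and Nutrition (APrON),mothers,Mothers,trimester2,Second trimester,0,0,7,5,35
APrON,Alberta Pregnancy Outcomes and Nutrition (APrON),mothers,Mothers,trimester3,Third trimester,0,7,6,6,29
APrON,Alberta Pregnancy Outcomes and Nutrition (APrON),mothers,Mothers,12w_postpartum,12 weeks postpartum,0,0,6,6,34
APrON,Alberta Pregnancy Outcomes and Nutrition (APrON),mothers,Mothers,24w_postpartum,24 weeks postpartum,0,0,2,2,0
APrON,Alberta Pregnancy Outcomes and Nutrition (APrON),mothers,Mothers,12m_postpartum,12 months postpartum,0,0,3,3,0
APrON,Alberta Pregnancy Outcomes and Nutrition (APrON),partners,Partners,trimester2,Second trimester,1,0,4,3,0
APrON,Alberta Pregnancy Outcomes and Nutrition (APrON),partners,Partners,12w_postpartum,12 weeks postpartum,0,0,3,2,0
APrON,Alberta Pregnancy Outcomes and Nutrition (APrON),children,Children,12w_postpartum,12 weeks postpartum,0,0,0,0,1
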