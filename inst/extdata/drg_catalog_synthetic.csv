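drg_code,label,total_cost,operating_room_cost,national_mean_los
04C021,"Major surgery on the thorax, level 1",9222.00,2600.00,7.0
04C022,"Major surgery on the thorax, level 2",12094.00,2600.00,9.5
04C023,"Major surgery on the thorax, level 3",16480.00,2600.00,13.0
04C024,"Major surgery on the thorax, level 4",22510.00,2600.00,18.0
0403B1,"Malignant tumours of the respiratory system, phy score >= 5, cog score <= 2, level 1",6222.20,0.00,21.0
04M051,"Pneumonia and pleurisy, age > 17, level 1",4205.00,0.00,6.2
04M052,"Pneumonia and pleurisy, age > 17, level 2",5510.00,0.00,8.4
05M091,"Heart failure and cardiogenic shock, level 1",4820.00,0.00,6.8
18M071,"Post-operative and post-traumatic infections, level 1",3610.00,0.00,5.5
04M161,"Pleural effusion, level 1",3110.00,0.00,4.6
23M061,"Other aftercare and convalescence, level 1",2690.00,0.00,3.9
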