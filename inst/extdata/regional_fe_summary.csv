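entity_id,trophic,habitat,tolerance,n_species,tni,ra_pct,obs_pct
FE-1,Omn,WC,IS,8,406,8.9,70.7
FE-2,Omn,WC,TS,6,217,4.7,48.8
FE-3,Ins,WC,IS,5,175,3.8,73.2
FE-4,Omn,BT,TS,4,32,0.7,26.8
FE-5,Ins,RB,SS,3,82,1.8,36.6
FE-6,Ins,WC,TS,3,170,3.7,46.3
FE-7,Ins,RB,IS,3,287,6.2,73.2
FE-8,Ins,RB-WC,IS,2,219,4.7,65.9
FE-9,Ins,BT,IS,2,263,5.7,78.0
FE-10,Car,WC,TS,2,93,2.0,51.2
FE-11,Car,BT,TS,2,3,0.1,7.3
FE-12,Car,BT,IS,2,70,1.5,53.7
FE-13,Car,BT,SS,2,33,0.7,31.7
FE-14,Omn,RB,IS,1,62,1.3,36.6
FE-15,Omn,RB,SS,1,49,1.1,12.2
FE-16,Ins,RB-WC,SS,1,353,7.6,34.1
FE-17,Omn,RB-WC,IS,1,2022,43.8,100.0
FE-18,Car,RB-WC,TS,1,77,1.7,31.7
FE-19,Ins,BT,TS,1,9,0.2,7.3
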