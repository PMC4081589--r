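case,device,outcome,axial_N_mm,shear_N_mm,shear_estimated,fe_computed,axial_pre_contact,gap_mm
1,Medially mounted monolateral external fixator,Torsional moment at failure after 9 weeks: 61.5% of contralateral intact tibia,2540,164,FALSE,FALSE,FALSE,3
2,Anteromedially mounted monolateral external fixator,Torsional moment at failure after 9 weeks: 83% of contralateral intact tibia,2177,433,FALSE,FALSE,FALSE,3
3,Rigid monolateral external fixator,Torsional moment at failure after 9 weeks: 68.2% of contralateral intact tibia,1523,374,FALSE,FALSE,FALSE,3
4,Semirigid monolateral external fixator,Torsional moment at failure after 9 weeks: 66.3% of contralateral intact tibia,1479,344,FALSE,FALSE,FALSE,3
5,Unreamed tibial nail,Torsional moment at failure after 9 weeks: 52.8% of contralateral intact tibia,1213,139,FALSE,FALSE,FALSE,3
6,Angle-stable tibial nail,Torsional moment at failure after 9 weeks: 64.1% of contralateral intact tibia,2762,469,FALSE,FALSE,FALSE,3
7,Locked plating,Torsional strength after 9 weeks: ~42% of contralateral intact tibia,3922,2500,FALSE,TRUE,FALSE,3
8,Far cortical locked plating,Torsional strength after 9 weeks: ~67% of contralateral intact tibia,628,600,TRUE,FALSE,TRUE,3
9,Mechanically critical external fixator,Torsional moment at failure after 9 weeks: 14% of contralateral intact tibia,650,50,TRUE,FALSE,FALSE,3
10,Unilateral external fixator,Bending stiffness after 6 weeks: 60% of contralateral intact tibia,183,170,FALSE,FALSE,FALSE,3
11,Rigid unilateral external fixator/actuator,Bending stiffness after 6 weeks: 24% of contralateral intact tibia,1666,220,TRUE,FALSE,FALSE,2
12,Rigid unilateral external fixator/actuator,Bending stiffness after 8 weeks: 60-69% of contralateral intact tibia,498,220,TRUE,FALSE,FALSE,2.6
13,Monolateral external fixator 35 mm pin offset,Week 6: advanced healing; week 12: bony bridging,500,350,TRUE,FALSE,FALSE,3
14,Monolateral external fixator 25 mm pin offset,Week 6: less advanced healing; week 12: bony bridging,700,350,TRUE,FALSE,FALSE,3
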