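level,variant,modality,activity,mean,sd
0.25,intact,bending,jumping_jack,33.1,13.3
0.25,intact,torsion,internal_rotation,19.8,11.7
0.25,intact,axial,jumping_jack,123.8,29.4
0.25,body_powered,bending,jumping_jack,22.9,2.6
0.25,body_powered,torsion,jug_lift,4.3,1.8
0.25,body_powered,axial,briefcase_carry,78.2,6.3
0.25,myoelectric_hook,bending,jug_lift,25.6,2.9
0.25,myoelectric_hook,torsion,internal_rotation,10.0,4.7
0.25,myoelectric_hook,axial,briefcase_carry,89.9,6.7
0.25,myoelectric_hand,bending,jumping_jack,29.8,8.5
0.25,myoelectric_hand,torsion,internal_rotation,15.9,7.4
0.25,myoelectric_hand,axial,briefcase_carry,94.5,7.0
0.25,advanced,bending,jumping_jack,58.8,16.8
0.25,advanced,torsion,internal_rotation,31.8,14.7
0.25,advanced,axial,jumping_jack,161.9,21.7
0.50,intact,bending,jumping_jack,26.3,10.3
0.50,intact,torsion,internal_rotation,19.8,11.7
0.50,intact,axial,jumping_jack,106.1,26.1
0.50,body_powered,bending,jug_lift,20.1,2.3
0.50,body_powered,torsion,jug_lift,4.3,1.8
0.50,body_powered,axial,briefcase_carry,77.8,6.3
0.50,myoelectric_hook,bending,jug_lift,22.3,2.5
0.50,myoelectric_hook,torsion,internal_rotation,10.0,4.7
0.50,myoelectric_hook,axial,briefcase_carry,89.5,6.7
0.50,myoelectric_hand,bending,jumping_jack,24.4,6.8
0.50,myoelectric_hand,torsion,internal_rotation,15.9,7.4
0.50,myoelectric_hand,axial,briefcase_carry,94.1,7.0
0.50,advanced,bending,jumping_jack,48.4,13.7
0.50,advanced,torsion,internal_rotation,31.8,14.7
0.50,advanced,axial,jumping_jack,160.9,21.8
0.75,intact,bending,jumping_jack,20.7,7.8
0.75,intact,torsion,internal_rotation,19.8,11.7
0.75,intact,axial,briefcase_carry,92.8,10.5
0.75,body_powered,bending,jug_lift,17.4,2.0
0.75,body_powered,torsion,jug_lift,4.3,1.8
0.75,body_powered,axial,briefcase_carry,75.8,6.1
0.75,myoelectric_hook,bending,jug_lift,19.1,2.2
0.75,myoelectric_hook,torsion,internal_rotation,10.0,4.7
0.75,myoelectric_hook,axial,briefcase_carry,87.5,6.6
0.75,myoelectric_hand,bending,jug_lift,20.1,2.3
0.75,myoelectric_hand,torsion,internal_rotation,15.9,7.4
0.75,myoelectric_hand,axial,briefcase_carry,92.1,6.9
0.75,advanced,bending,jumping_jack,38.9,10.7
0.75,advanced,torsion,internal_rotation,31.8,14.7
0.75,advanced,axial,jumping_jack,155.4,21.2
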