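ID,TIME,EVID,AMT,DV,MDV,BLQ,LLOQ,OCC,DRUG,SEX,WT,HT,HIV,ART,AGE,ALB,TPROT,ALCOHOL,DIABETES,PREVINH
S001,0,0,.,.,1,1,0.117,PREDOSE,RIFAMPIN,FEMALE,45.759478741004,1.4993000249551,1,NONE,18.6491330052382,43.2924991413413,88.6150413126093,0,0,1
S001,0,1,450,.,1,0,.,INTENSIVE,RIFAMPIN,FEMALE,45.759478741004,1.4993000249551,1,NONE,18.6491330052382,43.2924991413413,88.6150413126093,0,0,1
S001,1,0,.,2.18316285967995,0,0,0.117,INTENSIVE,RIFAMPIN,FEMALE,45.759478741004,1.4993000249551,1,NONE,18.6491330052382,43.2924991413413,88.6150413126093,0,0,1
S001,2,0,.,7.96358324435702,0,0,0.117,INTENSIVE,RIFAMPIN,FEMALE,45.759478741004,1.4993000249551,1,NONE,18.6491330052382,43.2924991413413,88.6150413126093,0,0,1
S001,3,0,.,7.30896398477895,0,0,0.117,INTENSIVE,RIFAMPIN,FEMALE,45.759478741004,1.4993000249551,1,NONE,18.6491330052382,43.2924991413413,88.6150413126093,0,0,1
S001,4,0,.,3.2758062877881,0,0,0.117,INTENSIVE,RIFAMPIN,FEMALE,45.759478741004,1.4993000249551,1,NONE,18.6491330052382,43.2924991413413,88.6150413126093,0,0,1
S001,6,0,.,1.50584358603615,0,0,0.117,INTENSIVE,RIFAMPIN,FEMALE,45.759478741004,1.4993000249551,1,NONE,18.6491330052382,43.2924991413413,88.6150413126093,0,0,1
S001,8,0,.,1.34014056425049,0,0,0.117,INTENSIVE,RIFAMPIN,FEMALE,45.759478741004,1.4993000249551,1,NONE,18.6491330052382,43.2924991413413,88.6150413126093,0,0,1
S002,0,0,.,0.167516756286358,0,0,0.117,PREDOSE,RIFAMPIN,MALE,71.7293784280259,1.64281878534573,1,PI_LPVR,29.428473014972,47.5333236911637,85.277971565539,0,0,0
S002,0,1,750,.,1,0,.,INTENSIVE,RIFAMPIN,MALE,71.7293784280259,1.64281878534573,1,PI_LPVR,29.428473014972,47.5333236911637,85.277971565539,0,0,0
S002,1,0,.,2.67651400943278,0,0,0.117,INTENSIVE,RIFAMPIN,MALE,71.7293784280259,1.64281878534573,1,PI_LPVR,29.428473014972,47.5333236911637,85.277971565539,0,0,0
S002,2,0,.,6.50482115337513,0,0,0.117,INTENSIVE,RIFAMPIN,MALE,71.7293784280259,1.64281878534573,1,PI_LPVR,29.428473014972,47.5333236911637,85.277971565539,0,0,0
S002,3,0,.,5.63629101397664,0,0,0.117,INTENSIVE,RIFAMPIN,MALE,71.7293784280259,1.64281878534573,1,PI_LPVR,29.428473014972,47.5333236911637,85.277971565539,0,0,0
S002,4,0,.,3.10660919162933,0,0,0.117,INTENSIVE,RIFAMPIN,MALE,71.7293784280259,1.64281878534573,1,PI_LPVR,29.428473014972,47.5333236911637,85.277971565539,0,0,0
S002,6,0,.,2.29464753219007,0,0,0.117,INTENSIVE,RIFAMPIN,MALE,71.7293784280259,1.64281878534573,1,PI_LPVR,29.428473014972,47.5333236911637,85.277971565539,0,0,0
S002,8,0,.,2.03106510090672,0,0,0.117,INTENSIVE,RIFAMPIN,MALE,71.7293784280259,1.64281878534573,1,PI_LPVR,29.428473014972,47.5333236911637,85.277971565539,0,0,0
S003,0,0,.,.,1,1,0.117,PREDOSE,RIFAMPIN,MALE,57.5919609123155,1.74531025592354,1,NNRTI,29.001343782507,30.8613167646694,103.682431320516,0,0,0
S003,0,1,600,.,1,0,.,INTENSIVE,RIFAMPIN,MALE,57.5919609123155,1.74531025592354,1,NNRTI,29.001343782507,30.8613167646694,103.682431320516,0,0,0
S003,1,0,.,2.27243718509605,0,0,0.117,INTENSIVE,RIFAMPIN,MALE,57.5919609123155,1.74531025592354,1,NNRTI,29.001343782507,30.8613167646694,103.682431320516,0,0,0
S003,2,0,.,2.65291682369916,0,0,0.117,INTENSIVE,RIFAMPIN,MALE,57.5919609123155,1.74531025592354,1,NNRTI,29.001343782507,30.8613167646694,103.682431320516,0,0,0
S003,3,0,.,2.32385149359892,0,0,0.117,INTENSIVE,RIFAMPIN,MALE,57.5919609123155,1.74531025592354,1,NNRTI,29.001343782507,30.8613167646694,103.682431320516,0,0,0
S003,4,0,.,1.91378295143765,0,0,0.117,INTENSIVE,RIFAMPIN,MALE,57.5919609123155,1.74531025592354,1,NNRTI,29.001343782507,30.8613167646694,103.682431320516,0,0,0
S003,6,0,.,1.06449524622109,0,0,0.117,INTENSIVE,RIFAMPIN,MALE,57.5919609123155,1.74531025592354,1,NNRTI,29.001343782507,30.8613167646694,103.682431320516,0,0,0
S003,8,0,.,0.410394017153646,0,0,0.117,INTENSIVE,RIFAMPIN,MALE,57.5919609123155,1.74531025592354,1,NNRTI,29.001343782507,30.8613167646694,103.682431320516,0,0,0
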