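model,unit_code,orientation,lower_khz,upper_khz
HC600,HC600-1,front,3,35
HC600,HC600-2,front,3,20
HC600,HC600-3,front,3,50
HC600,HC600-4,front,3,55
HC600,HC600-5,front,3,60
HC600,HC600-6,front,3,55
HC600,HC600-7,front,0,0
HC600,HC600-8,front,3,55
HC600,HC600-9,front,0,0
HC600,HC600-10,front,3,50
HC600,HC600-1,offset45,3,40
HC600,HC600-2,offset45,3,35
HC600,HC600-3,offset45,3,45
HC600,HC600-4,offset45,3,50
HC600,HC600-5,offset45,3,55
HC600,HC600-6,offset45,3,0
HC600,HC600-7,offset45,0,0
HC600,HC600-8,offset45,3,50
HC600,HC600-9,offset45,0,0
HC600,HC600-10,offset45,3,45
Cuddeback,Cuddeback-1,front,3,40
Cuddeback,Cuddeback-2,front,3,40
Cuddeback,Cuddeback-3,front,3,60
Cuddeback,Cuddeback-1,offset45,3,55
Cuddeback,Cuddeback-2,offset45,3,60
Cuddeback,Cuddeback-3,offset45,3,40
Pixcontroller,Pixcontroller-1,front,0,0
Pixcontroller,Pixcontroller-2,front,0,0
Pixcontroller,Pixcontroller-3,front,3,35
Pixcontroller,Pixcontroller-1,offset45,0,0
Pixcontroller,Pixcontroller-2,offset45,3,45
Pixcontroller,Pixcontroller-3,offset45,0,0
Scoutguard 560D,Scoutguard 560D-1,front,3,0
Scoutguard 560D,Scoutguard 560D-1,offset45,0,0
Uway NT50,Uway NT50-1,front,3,35
Uway NT50,Uway NT50-1,offset45,3,0
Control,Control 1,front,0,0
Control,Control 1,offset45,0,0
Control,Control 2,front,0,0
Control,Control 2,offset45,0,0
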