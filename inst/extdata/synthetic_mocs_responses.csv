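"participant","intensity","correct","pas"
"sim01",0,1,0
"sim01",0,1,0
"sim01",0,0,2
"sim01",0,0,0
"sim01",0,1,0
"sim01",0,0,1
"sim01",0,0,2
"sim01",0,0,0
"sim01",8.33,1,3
"sim01",8.33,1,0
"sim01",8.33,1,1
"sim01",8.33,1,0
"sim01",8.33,1,1
"sim01",8.33,1,0
"sim01",8.33,0,3
"sim01",8.33,0,1
"sim01",16.67,0,0
"sim01",16.67,1,0
"sim01",16.67,1,0
"sim01",16.67,0,3
"sim01",16.67,1,3
"sim01",16.67,1,0
"sim01",16.67,0,0
"sim01",16.67,1,1
"sim01",25,1,0
"sim01",25,0,0
"sim01",25,1,2
"sim01",25,1,0
"sim01",25,0,1
"sim01",25,0,2
"sim01",25,0,3
"sim01",25,0,0
"sim01",33.33,0,3
"sim01",33.33,1,0
"sim01",33.33,0,0
"sim01",33.33,0,2
"sim01",33.33,1,2
"sim01",33.33,0,3
"sim01",33.33,1,2
"sim01",33.33,1,3
"sim01",58.33,1,3
"sim01",58.33,1,0
"sim01",58.33,1,3
"sim01",58.33,1,2
"sim01",58.33,1,1
"sim01",58.33,0,3
"sim01",58.33,1,2
"sim01",58.33,0,0
"sim01",100,1,1
"sim01",100,1,2
"sim01",100,1,2
"sim01",100,1,1
"sim01",100,1,3
"sim01",100,1,0
"sim01",100,1,2
"sim01",100,1,1
"sim01",141.7,1,2
"sim01",141.7,1,1
"sim01",141.7,1,2
"sim01",141.7,1,1
"sim01",141.7,1,1
"sim01",141.7,1,1
"sim01",141.7,1,1
"sim01",141.7,1,1
"sim01",200,1,1
"sim01",200,1,1
"sim01",200,1,2
"sim01",200,1,3
"sim01",200,1,3
"sim01",200,1,3
"sim01",200,1,2
"sim01",200,1,2
"sim02",0,1,0
"sim02",0,1,0
"sim02",0,0,2
"sim02",0,0,0
"sim02",0,1,0
"sim02",0,0,1
"sim02",0,0,2
"sim02",0,0,0
"sim02",8.33,1,3
"sim02",8.33,1,0
"sim02",8.33,1,1
"sim02",8.33,1,0
"sim02",8.33,1,1
"sim02",8.33,1,0
"sim02",8.33,0,3
"sim02",8.33,0,1
"sim02",16.67,0,0
"sim02",16.67,1,0
"sim02",16.67,1,0
"sim02",16.67,0,3
"sim02",16.67,1,3
"sim02",16.67,1,0
"sim02",16.67,0,0
"sim02",16.67,1,1
"sim02",25,1,0
"sim02",25,1,0
"sim02",25,1,2
"sim02",25,1,0
"sim02",25,0,1
"sim02",25,0,2
"sim02",25,0,0
"sim02",25,0,0
"sim02",33.33,0,3
"sim02",33.33,1,0
"sim02",33.33,0,0
"sim02",33.33,0,2
"sim02",33.33,1,2
"sim02",33.33,0,3
"sim02",33.33,1,2
"sim02",33.33,1,3
"sim02",58.33,1,3
"sim02",58.33,1,0
"sim02",58.33,1,3
"sim02",58.33,0,2
"sim02",58.33,1,1
"sim02",58.33,0,3
"sim02",58.33,1,2
"sim02",58.33,0,0
"sim02",100,1,1
"sim02",100,1,2
"sim02",100,1,2
"sim02",100,1,1
"sim02",100,1,3
"sim02",100,1,0
"sim02",100,1,2
"sim02",100,1,1
"sim02",141.7,1,2
"sim02",141.7,1,1
"sim02",141.7,1,2
"sim02",141.7,1,1
"sim02",141.7,1,1
"sim02",141.7,1,1
"sim02",141.7,1,1
"sim02",141.7,1,1
"sim02",200,1,1
"sim02",200,1,1
"sim02",200,1,2
"sim02",200,1,3
"sim02",200,1,3
"sim02",200,1,3
"sim02",200,1,2
"sim02",200,1,2
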