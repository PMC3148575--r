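indicator,category,band,pct_male,pct_female,pct_total
self_report,1,"< $20,000",20.3,33.7,30.2
self_report,2,"$20,000-$29,999",31.6,21.4,24.1
self_report,3,"$30,000-$49,999",26.6,19.0,21.0
self_report,4,"$50,000-$69,999",13.0,12.4,12.6
self_report,5,">= $70,000",8.5,13.4,12.1
residential,1,"<= $42,102",28.2,30.7,30.0
residential,2,"$42,103-$66,629",27.1,22.8,24.0
residential,3,"$66,630-$94,975",22.6,20.4,21.0
residential,4,"$94,976-$133,176",13.6,12.8,13.0
residential,5,">= $133,177",8.5,13.2,12.0
census,1,"<= $25,781",29.9,30.7,30.5
census,2,"$25,782-$31,434",22.0,24.4,23.8
census,3,"$31,435-$39,255",24.9,19.2,20.7
census,4,"$39,256-$49,776",13.0,13.0,13.0
census,5,">= $49,777",10.2,12.6,12.0
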