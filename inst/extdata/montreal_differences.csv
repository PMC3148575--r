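comparison,difference,count,pct
residential,<=-3,21,3.1
residential,-2,60,8.9
residential,-1,129,19.1
residential,0,259,38.3
residential,1,125,18.5
residential,2,56,8.3
residential,>=3,26,3.9
census,<=-3,36,5.3
census,-2,65,9.6
census,-1,139,20.6
census,0,200,29.6
census,1,129,19.1
census,2,74,10.9
census,>=3,33,4.8
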