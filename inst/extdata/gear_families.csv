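"gear","family"
"gillnets","nets"
"liftnets","nets"
"seines","nets"
"surrounding nets","nets"
"bottom trawls","trawls"
"midwater trawls","trawls"
"lines","lines"
"longlines","lines"
"pole and line","lines"
"pots and traps","traps"
"dredges","dredges"
"others","others"
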