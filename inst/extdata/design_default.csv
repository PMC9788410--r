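product_id,oil_type,tomato_dose,yeast_product,yeast_dose,heat
P01,corn,high,S99,low,short
P02,olive,low,S99,low,long
P03,corn,low,S99,low,long
P04,corn,high,S99,high,short
P05,olive,low,S99,high,long
P06,corn,low,S99,high,long
P07,corn,high,G28,low,short
P08,olive,low,G28,low,long
P09,corn,low,G28,low,long
P10,corn,high,G28,high,short
P11,olive,low,G28,high,long
P12,corn,low,G28,high,long
P13,corn,high,O31,low,short
P14,olive,low,O31,low,long
P15,corn,low,O31,low,long
P16,corn,high,O31,high,short
P17,olive,low,O31,high,long
P18,corn,low,O31,high,long
P19,corn,high,YPr,low,short
P20,olive,low,YPr,low,long
P21,corn,low,YPr,low,long
P22,corn,high,YPr,high,short
P23,olive,low,YPr,high,long
P24,corn,low,YPr,high,long
P25,corn,high,none,none,short
P26,olive,low,none,none,long
P27,corn,low,none,none,long
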