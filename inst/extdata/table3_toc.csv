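sample_id,site_name,TOC
No.1,Suez,2.31
No.2,Ain Sukhna,1.64
No.3,Zaafarana N.,1.52
No.4,Zaafarana S.,1.52
No.5,Ras Gharib,1.57
No.6,Ras Shokier,1.54
No.7,Gabal El Zeit,1.63
No.8,Qusier,1.63
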