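line,class,zone,staining,delta_pi
synthPAM01,PAM,b1,4,0.52
synthPAM01,PAM,b2,3,0.52
synthPAM02,PAM,b2,5,0.31
synthPAM02,PAM,bp2,2,0.31
synthPAM03,PAM,g4,4,-0.18
synthPAM03,PAM,g5,3,-0.18
synthMBON01,MBON,b2,3,-0.44
synthMBON01,MBON,bp2,4,-0.44
synthMBON02,MBON,g4,5,0.22
synthMBON02,MBON,g5,3,0.22
synthMBON03,MBON,a1,4,0.05
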