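task,variable,mdc95
RSEO,COP mean speed,2.3
RSEO,RMS,2.6
RSEO,Area,1.4
RSEO,AP disp.,11.6
RSEO,ML disp.,7.1
RSEC,COP mean speed,3.3
RSEC,RMS,1.9
RSEC,Area,2.0
RSEC,AP disp.,9.7
RSEC,ML disp.,8.7
SSEO,COP mean speed,2.5
SSEO,RMS,2.0
SSEO,Area,1.5
SSEO,AP disp.,8.8
SSEO,ML disp.,7.7
SSEC,COP mean speed,8.5
SSEC,RMS,3.0
SSEC,Area,7.2
SSEC,AP disp.,20.4
SSEC,ML disp.,21.4
LOS,COP mean speed,2.3
LOS,RMS,0.2
LOS,Area,21.7
LOS,AP disp.,14.4
LOS,ML disp.,14.8
LOS,Lim.COP.Forward,15.0
LOS,Lim.COP.Forward-rightward,10.2
LOS,Lim.COP.Rightward,14.0
LOS,Lim.COP.Backward-rightward,11.4
LOS,Lim.COP.Backward,15.6
LOS,Lim.COP.Backward-leftward,14.4
LOS,Lim.COP.Leftward,13.1
LOS,Lim.COP.Forward-leftward,12.5
LOS,Success.Forward,25.8
LOS,Success.Forward-rightward,13.2
LOS,Success.Rightward,18.1
LOS,Success.Backward-rightward,23.0
LOS,Success.Backward,18.5
LOS,Success.Backward-leftward,27.7
LOS,Success.Leftward,14.4
LOS,Success.Forward-leftward,16.5
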