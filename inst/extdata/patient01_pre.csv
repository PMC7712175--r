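task,variable,units,value
RSEO,COP mean speed,mm/s,13.3
RSEO,RMS,mm,6.5
RSEO,Area,cm^2,3.4
RSEO,AP disp.,mm,20.0
RSEO,ML disp.,mm,22.4
RSEC,COP mean speed,mm/s,20.3
RSEC,RMS,mm,7.6
RSEC,Area,cm^2,5.1
RSEC,AP disp.,mm,26.9
RSEC,ML disp.,mm,30.4
SSEO,COP mean speed,mm/s,18.5
SSEO,RMS,mm,7.3
SSEO,Area,cm^2,4.9
SSEO,AP disp.,mm,23.3
SSEO,ML disp.,mm,44.3
SSEC,COP mean speed,mm/s,62.6
SSEC,RMS,mm,19.2
SSEC,Area,cm^2,41.0
SSEC,AP disp.,mm,102.4
SSEC,ML disp.,mm,66.5
LOS,COP mean speed,mm/s,19.0
LOS,RMS,mm,5.5
LOS,Area,cm^2,170.0
LOS,AP disp.,mm,154.9
LOS,ML disp.,mm,150.3
LOS,Lim.COP.Forward,mm,86.8
LOS,Lim.COP.Forward-rightward,mm,9.5
LOS,Lim.COP.Rightward,mm,0.0
LOS,Lim.COP.Backward-rightward,mm,60.4
LOS,Lim.COP.Backward,mm,32.7
LOS,Lim.COP.Backward-leftward,mm,60.0
LOS,Lim.COP.Leftward,mm,72.7
LOS,Lim.COP.Forward-leftward,mm,106.6
LOS,Success.Forward,%,50.7
LOS,Success.Forward-rightward,%,69.0
LOS,Success.Rightward,%,43.9
LOS,Success.Backward-rightward,%,45.3
LOS,Success.Backward,%,53.9
LOS,Success.Backward-leftward,%,43.6
LOS,Success.Leftward,%,55.9
LOS,Success.Forward-leftward,%,58.5
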