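task,variable,units,value
RSEO,COP mean speed,mm/s,11.2
RSEO,RMS,mm,5.0
RSEO,Area,cm^2,2.1
RSEO,AP disp.,mm,17.0
RSEO,ML disp.,mm,17.7
RSEC,COP mean speed,mm/s,16.9
RSEC,RMS,mm,7.5
RSEC,Area,cm^2,3.3
RSEC,AP disp.,mm,31.6
RSEC,ML disp.,mm,20.0
SSEO,COP mean speed,mm/s,18.0
SSEO,RMS,mm,6.8
SSEO,Area,cm^2,3.7
SSEO,AP disp.,mm,23.3
SSEO,ML disp.,mm,28.4
SSEC,COP mean speed,mm/s,49.4
SSEC,RMS,mm,15.0
SSEC,Area,cm^2,25.4
SSEC,AP disp.,mm,62.2
SSEC,ML disp.,mm,72.5
LOS,COP mean speed,mm/s,21.2
LOS,RMS,mm,6.2
LOS,Area,cm^2,234.0
LOS,AP disp.,mm,176.8
LOS,ML disp.,mm,179.5
LOS,Lim.COP.Forward,mm,108.2
LOS,Lim.COP.Forward-rightward,mm,108.3
LOS,Lim.COP.Rightward,mm,92.8
LOS,Lim.COP.Backward-rightward,mm,72.5
LOS,Lim.COP.Backward,mm,69.0
LOS,Lim.COP.Backward-leftward,mm,82.1
LOS,Lim.COP.Leftward,mm,87.0
LOS,Lim.COP.Forward-leftward,mm,104.7
LOS,Success.Forward,%,68.8
LOS,Success.Forward-rightward,%,73.6
LOS,Success.Rightward,%,88.2
LOS,Success.Backward-rightward,%,81.5
LOS,Success.Backward,%,91.9
LOS,Success.Backward-leftward,%,70.2
LOS,Success.Leftward,%,75.1
LOS,Success.Forward-leftward,%,79.2
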