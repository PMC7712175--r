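task,variable,units,mean_test,sd_test,mean_retest,sd_retest,icc,mdc95_es,mdc95,star
RSEO,COP mean speed,mm/s,8.1,2.3,8.4,2.2,0.87,0.9,2.3,TRUE
RSEO,RMS,mm,5.1,1.2,5.3,1.7,0.61,2.1,2.6,FALSE
RSEO,Area,cm^2,1.7,0.9,1.7,0.9,0.71,1.5,1.4,FALSE
RSEO,AP disp.,mm,19,4.7,19.5,6.1,0.42,2.4,11.6,FALSE
RSEO,ML disp.,mm,15.8,4.4,15.8,4.8,0.70,1.5,7.1,FALSE
RSEC,COP mean speed,mm/s,13.9,4.2,13.6,3.9,0.92,0.7,3.3,TRUE
RSEC,RMS,mm,6.2,1.9,6.5,1.8,0.87,0.9,1.9,TRUE
RSEC,Area,cm^2,3.5,1.9,3.4,1.8,0.85,1.0,2.0,TRUE
RSEC,AP disp.,mm,24.3,6.1,25.9,7.7,0.75,1.5,9.7,FALSE
RSEC,ML disp.,mm,22.4,8.3,22.7,7.6,0.85,1.0,8.7,TRUE
SSEO,COP mean speed,mm/s,13.7,2.7,13.5,2.3,0.88,0.9,2.5,TRUE
SSEO,RMS,mm,6.9,1.3,6.9,1.5,0.74,1.4,2.0,FALSE
SSEO,Area,cm^2,3.7,1.0,3.4,1.1,0.76,0.4,1.5,FALSE
SSEO,AP disp.,mm,27.5,5.1,27.2,6.7,0.72,1.7,8.8,FALSE
SSEO,ML disp.,mm,23.4,4.3,22.2,4,0.56,1.7,7.7,FALSE
SSEC,COP mean speed,mm/s,36.2,7.9,34,6.6,0.83,1.0,8.5,TRUE
SSEC,RMS,mm,13.6,2.2,13.3,2.3,0.77,1.3,3.0,FALSE
SSEC,Area,cm^2,17.2,5.3,15.7,4.7,0.74,1.3,7.2,FALSE
SSEC,AP disp.,mm,54.8,12.4,52.7,10.9,0.61,1.6,20.4,FALSE
SSEC,ML disp.,mm,51.6,10.6,50.4,9.5,0.42,2.0,21.4,FALSE
LOS,COP mean speed,mm/s,15.9,3.1,15.4,3.0,0.93,0.7,2.3,TRUE
LOS,RMS,mm,5.8,0.3,5.9,0.3,0.96,0.5,0.2,TRUE
LOS,Area,cm^2,179.5,43.7,183.2,45.2,0.97,0.4,21.7,TRUE
LOS,AP disp.,mm,153.8,20.4,157,19.7,0.94,0.7,14.4,FALSE
LOS,ML disp.,mm,157.1,20,158,23.1,0.94,0.7,14.8,FALSE
LOS,Lim.COP.Forward,mm,84.6,17.5,87.5,15.3,0.90,0.8,15.0,TRUE
LOS,Lim.COP.Forward-rightward,mm,90.4,14.4,91.8,11.8,0.93,0.7,10.2,TRUE
LOS,Lim.COP.Rightward,mm,77.3,12.2,75.5,12.2,0.83,1.1,14.0,FALSE
LOS,Lim.COP.Backward-rightward,mm,68.2,12.7,68,10.6,0.88,0.8,11.4,FALSE
LOS,Lim.COP.Backward,mm,68.1,14.3,68.5,13.6,0.84,1.0,15.6,FALSE
LOS,Lim.COP.Backward-leftward,mm,71.2,12.2,71,14.1,0.85,1.1,14.4,FALSE
LOS,Lim.COP.Leftward,mm,77.6,10.5,81.4,13.8,0.86,1.2,13.1,FALSE
LOS,Lim.COP.Forward-leftward,mm,91,14.8,92.6,12.4,0.89,0.8,12.5,TRUE
LOS,Success.Forward,%,75.7,14.4,76.8,11.7,0.50,1.7,25.8,FALSE
LOS,Success.Forward-rightward,%,79.4,12.2,79.1,13.9,0.87,1.0,13.2,FALSE
LOS,Success.Rightward,%,78.3,12.3,80.4,10.7,0.68,1.4,18.1,FALSE
LOS,Success.Backward-rightward,%,79.1,11.6,78,9.9,0.42,1.9,23.0,FALSE
LOS,Success.Backward,%,83.5,11.0,85.6,8.2,0.57,1.5,18.5,FALSE
LOS,Success.Backward-leftward,%,80.4,10.5,82.8,11.7,0.20,2.6,27.7,FALSE
LOS,Success.Leftward,%,80.8,11.7,81.6,11.1,0.80,1.2,14.4,FALSE
LOS,Success.Forward-leftward,%,78.8,13.3,80.5,11.4,0.77,1.2,16.5,FALSE
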