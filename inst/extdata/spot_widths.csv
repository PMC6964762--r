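metric,position,energy_mev,film_mm,lynx_mm,raw_diff_mm,percent_diff
fwhm,Z0,70,12.5,12.6,-0.1,-0.9
fwhm,Z0,80,11.5,11.8,-0.3,-2.3
fwhm,Z0,90,10.7,11.2,-0.5,-4.6
fwhm,Z0,100,9.8,10.7,-1.0,-9.4
fwhm,Z0,130,9.5,9.9,-0.4,-3.9
fwhm,Z0,150,9.4,9.5,0.0,-0.4
fwhm,Z0,180,9.1,9.2,-0.2,-1.9
fwhm,Z0,210,9.0,8.7,0.3,3.6
fwhm,Z0,242,8.7,8.7,0.1,0.7
fwhm,Z300,70,9.4,9.2,0.2,2.6
fwhm,Z300,80,9.4,8.9,0.5,5.4
fwhm,Z300,90,8.8,8.5,0.3,2.9
fwhm,Z300,100,8.3,8.4,-0.1,-1.5
fwhm,Z300,130,8.5,8.1,0.4,4.6
fwhm,Z300,150,8.8,7.9,0.9,10.6
fwhm,Z300,180,8.8,8.3,0.5,6.2
fwhm,Z300,210,8.7,7.9,0.8,9.2
fwhm,Z300,242,8.4,8.2,0.2,2.2
fw10,Z0,70,24.1,24.2,-0.1,-0.6
fw10,Z0,80,22.0,22.3,-0.3,-1.5
fw10,Z0,90,20.2,21.0,-0.8,-3.9
fw10,Z0,100,18.8,19.9,-1.1,-5.5
fw10,Z0,130,17.4,18.2,-0.8,-4.4
fw10,Z0,150,16.9,17.5,-0.6,-3.6
fw10,Z0,180,15.9,16.5,-0.7,-4.1
fw10,Z0,210,15.2,15.5,-0.4,-2.4
fw10,Z0,242,14.5,14.5,0.0,-0.1
fw10,Z300,70,17.3,17.5,-0.2,-1.3
fw10,Z300,80,16.3,16.5,-0.3,-1.6
fw10,Z300,90,15.3,15.8,-0.4,-2.7
fw10,Z300,100,14.7,15.3,-0.6,-3.8
fw10,Z300,130,14.0,14.5,-0.5,-3.5
fw10,Z300,150,14.3,14.0,0.2,1.7
fw10,Z300,180,14.0,13.5,0.4,3.3
fw10,Z300,210,13.8,13.0,0.8,6.1
fw10,Z300,242,13.4,13.0,0.4,2.9
fw1,Z0,70,36.1,37.6,-1.5,-4.1
fw1,Z0,80,32.8,33.6,-0.8,-2.4
fw1,Z0,90,30.0,31.7,-1.7,-5.5
fw1,Z0,100,28.0,30.0,-1.9,-6.7
fw1,Z0,130,25.1,26.9,-1.7,-6.7
fw1,Z0,150,23.9,25.8,-1.8,-7.3
fw1,Z0,180,22.2,24.0,-1.9,-8.1
fw1,Z0,210,20.9,22.4,-1.6,-7.2
fw1,Z0,242,19.7,20.8,-1.1,-5.6
fw1,Z300,70,25.5,26.2,-0.8,-2.9
fw1,Z300,80,23.9,24.7,-0.7,-3.0
fw1,Z300,90,22.5,23.2,-0.7,-3.1
fw1,Z300,100,21.2,22.3,-1.1,-5.1
fw1,Z300,130,19.8,20.7,-1.0,-4.9
fw1,Z300,150,19.6,20.0,-0.4,-2.0
fw1,Z300,180,19.0,19.3,-0.3,-1.4
fw1,Z300,210,18.5,18.3,0.2,1.2
fw1,Z300,242,17.8,17.3,0.5,2.9
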