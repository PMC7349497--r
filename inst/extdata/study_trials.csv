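trial,actual_g,recall24hr_est_g,recall24hr_err_g,myfitnesspal_est_g,myfitnesspal_err_g,dietsensor_est_g,dietsensor_err_g
1,19,34,15,78,59,30,11
2,100,42,-58,52,-48,122,22
3,30,39,9,NA,NA,80,50
4,121,46,-75,NA,NA,94,-27
5,18,59,41,NA,NA,25,7
6,61,58,-3,156,95,62,1
7,46,49,3,68,22,39,-7
8,78,75,-3,56,-22,39,-39
9,61,44,-17,NA,NA,28,-33
10,86,24,-62,17,-69,104,18
11,14,129,115,NA,NA,7,-7
12,58,26,-32,50,-8,35,-23
13,84,13,-71,17,-67,94,10
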