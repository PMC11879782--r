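measure,domain,n,ci_low,ci_high,d_printed,p_printed,units
PROMIS,behavioral,8,-5.52,-1.73,1.601,0.003,score
TMT_A,behavioral,8,-13.97,4.76,0.411,0.283,s
TMT_B,behavioral,8,-29.01,5.78,0.558,0.158,s
microstate_A_duration,microstate,8,3.51,24.15,1.120,0.016,ms
microstate_C_duration,microstate,8,0.50,25.47,0.869,0.044,ms
microstate_D_duration,microstate,8,3.87,16.75,1.339,0.007,ms
microstate_G_duration,microstate,8,0.40,17.67,0.875,0.043,ms
microstate_B_occurrence,microstate,8,-3.82,-0.50,1.090,0.018,Hz
microstate_F_occurrence,microstate,8,-2.66,-0.20,0.971,0.029,Hz
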