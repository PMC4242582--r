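site,top_mean,top_sd,bottom_mean,bottom_sd,bottom_pct_mean,bottom_pct_sd
Sylt-Romo Wadden Sea,1.73,0.94,14.85,13.4,80.09,24.07
Western Wadden Sea,1.42,1.35,8.06,5.32,89.02,9.65
The Wash,1.58,1.31,2.22,1.94,64.99,16.98
Dutch Delta,1.11,0.67,7.82,6.58,75.28,25.61
Dublin bay,0.47,0.65,7.35,2.96,93.25,10.13
Re island,0.39,0.26,1.75,2.26,80.79,22.33
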