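site,lat,lon,t_air_c,wind_ms,radiation_wm2,distance_km_override
Sylt-Romo Wadden Sea,55.0167,8.4333,0,7,45,1940
Western Wadden Sea,53.2333,5.25,2,7.5,50,2196
The Wash,52.9333,0.3167,4,6.5,55,2357
Dutch Delta,51.6667,4.1167,3,6.8,52,2388
Dublin bay,53.3167,-6.1833,5,6,55,2502
Re island,46.25,-1.4833,7,5.5,75,3093
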