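dataset,nominal_dose_kgy,dose_rate_mgy_s,transmission_pct,frame_rate_hz,n_images,n_hits,n_indexed,hit_rate_printed,index_rate_printed
L21k-1,21,2.1,9.49,100,22200,8977,6715,40.4,74.8
L21k-2,21,2.1,9.49,100,22200,9581,7371,43.2,76.9
L42k-1,42,4.2,19.4,100,22200,9617,7696,43.3,80.0
L42k-2,42,4.2,19.4,100,22200,13657,9548,61.5,69.9
L83k-1,83,8.3,40.1,100,22200,12783,9240,57.6,72.3
L83k-2,83,8.3,40.1,100,22200,7987,6557,36.0,82.1
L210k-1,210,21,94.2,100,22200,9803,5677,44.2,57.9
L210k-2,210,21,94.2,100,22200,5099,4003,23.0,78.5
L420k-1,420,23,100,54,22200,12583,7615,56.7,60.5
L420k-2,420,23,100,54,22200,6404,4591,28.8,71.7
L830k-1,830,23,100,27,22200,5081,3320,22.9,65.3
L830k-2,830,23,100,27,22200,15322,6886,69.0,44.9
L1700k-1,1700,23,100,13,22200,9856,5167,44.4,52.4
L1700k-2,1700,23,100,13,22200,3471,2691,15.6,77.5
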