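site,latitude,longitude,crop,irrigation_type,sowing_date,harvest_date,rainfall_total_mm,rainfall_season_mm
US-Ne1,41.1653,-96.4766,continuous maize,center pivot,2019-04-19,2019-11-05,910.97,764.92
US-Ne2,41.164,-96.4701,maize-soybean rotation,center pivot,2019-04-23,2019-11-07,896.87,752.86
US-Ne3,41.179,-96.439,maize-soybean rotation,rainfed,2019-04-24,2019-11-07,803.60,655.90
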