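site,date,depth_mm
US-Ne1,2019-06-13,6.35
US-Ne1,2019-07-01,6.35
US-Ne1,2019-07-08,30.48
US-Ne1,2019-07-15,30.48
US-Ne1,2019-07-24,0.4
US-Ne1,2019-07-29,31.75
US-Ne1,2019-08-09,31.75
US-Ne2,2019-07-02,30.48
US-Ne2,2019-07-08,30.48
US-Ne2,2019-07-15,30.48
US-Ne2,2019-07-29,30.48
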