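"treatment","replicate","n2_fix_per_cell","c_fix_per_cell","poc","pon","pop"
"ambient","1",1.55066045272408,21.6606297105803,340.190726810594,47.2726352220846,0.969415439314479
"ambient","2",1.61475912259851,20.3322371245548,344.48522599308,51.7689251839861,0.895175944173609
"ambient","3",1.53452701288152,19.1961330354997,341.696882814253,48.9448019696682,1.05785846226257
"acidified","1",1.11748654242039,17.2958009971835,269.287726888278,40.5989157091059,1.1892495271618
"acidified","2",1.11909371214192,17.1003299975265,259.927269394864,39.2496934971298,1.24976130262083
"acidified","3",1.17412183750882,17.3805465071486,234.441484763999,39.0545855422019,1.30702969707573
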