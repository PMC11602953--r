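dataset,arm,visit,on,off_obs,off_miss
covered,reference,1,88,0,0
covered,reference,2,81,3,4
covered,reference,3,76,7,5
covered,reference,4,65,12,11
covered,active,1,84,0,0
covered,active,2,78,4,2
covered,active,3,73,5,6
covered,active,4,64,10,10
perforated,reference,1,88,0,0
perforated,reference,2,81,5,2
perforated,reference,3,76,9,3
perforated,reference,4,65,12,11
perforated,active,1,84,0,0
perforated,active,2,78,0,6
perforated,active,3,73,4,7
perforated,active,4,64,10,10
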