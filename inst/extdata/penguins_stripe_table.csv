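0,0,0,0,0,0,0,0,0,0,2,1
1,1,1,5,0,0,2,0,5,3,2,0
,3,5,9,6,8,2,5,5,0,0,
,0,3,5,5,7,6,9,1,2,0,
,,1,0,0,4,4,1,1,0,,
,,0,2,4,0,1,0,0,0,,
,,,0,0,0,0,1,0,,,
,,,0,0,0,0,0,0,,,
,,,,0,0,0,0,,,,
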