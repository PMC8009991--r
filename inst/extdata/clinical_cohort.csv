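subject_id,arm,stimulation_sites,baseline_seizures,followup_seizures
S01,active,C3-FC1,80,77
S02,active,F7,1,4
S03,active,F4,1,1
S04,active,F4,1,3
S05,active,F7,3,1
S06,active,F7,10,14
S07,active,F8,9,7
S08,active,C3-F3,7,14
S09,active,F7;F8,12,9
S10,active,F7;F8,5,10
S11,active,F4-Fz,28,28
S12,active,F7,1,0
S13,sham,C3-FC1,56,66
S14,sham,CP6,2,2
S15,sham,F7,3,2
S16,sham,F7,6,8
S17,sham,C4-P4,2,1
S18,sham,C3-F3,14,9
S19,sham,F8,6,6
S20,sham,F7;F8,6,4
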