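seq_id,clone_id,is_chimera
c001_s01,1,FALSE
c001_s02,1,FALSE
c001_s03,1,FALSE
c002_s01,2,FALSE
c002_s02,2,FALSE
c002_s03,2,FALSE
c002_s04,2,FALSE
c003_s01,3,FALSE
c003_s02,3,FALSE
c004_s01,4,FALSE
c004_s02,4,FALSE
c004_s03,4,FALSE
c004_s04,4,FALSE
c005_s01,5,FALSE
c005_s02,5,FALSE
c005_s03,5,FALSE
c005_s04,5,FALSE
c006_s01,6,FALSE
c006_s02,6,FALSE
c007_s01,7,FALSE
c007_s02,7,FALSE
c008_s01,8,FALSE
c008_s02,8,FALSE
c009_s01,9,FALSE
c009_s02,9,FALSE
c009_s03,9,FALSE
c010_s01,10,FALSE
c010_s02,10,FALSE
c010_s03,10,FALSE
c010_s04,10,FALSE
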