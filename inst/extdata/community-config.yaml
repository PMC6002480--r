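# Example community-generator configuration for mingle-pipeline.R
# (simulate --type community --config <this file>)
abundance:
  maple: 300
  linden: 200
  pine: 100
  fir: 50
dbh_mean: [11, 13, 16, 32]
dbh_sd: [4, 4, 5, 6]
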