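{
  "effectors": 1,
  "suppressors": -1,
  "Th1": 1,
  "Th2": -1,
  "MHC": 1,
  "costimulators": 1,
  "coinhibitors": -1
}
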