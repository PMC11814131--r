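# Illustrative regionalization of a meridional basin into four latitude
# bands with their winter blooming windows (start month, end month).
# These bounds are NOT authoritative: region boundaries are a mandatory
# configuration input and must be supplied by the analyst.
regions:
  NRS:  {lat: [25.5, 28.5], lon: [32.0, 39.0], bloom: [1, 3]}
  NCRS: {lat: [22.0, 25.5], lon: [35.0, 40.0], bloom: [12, 2]}
  SCRS: {lat: [18.0, 22.0], lon: [37.0, 42.0], bloom: [12, 2]}
  SRS:  {lat: [13.0, 18.0], lon: [39.0, 43.5], bloom: [10, 1]}
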