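# Example pipeline configuration. Unset keys keep package defaults.
simulation:
  seed: 1
  nCellsPerGroup: 300
  nXGenes: 240
  nChr9Genes: 100
  nOtherGenes: 1200
  dispersion: 0.3
  depthLognormalSigma: 0.3
  markerFold: 4
qc:
  minGenes: 500
  minUMIs: 1000
  maxMitoFraction: 0.05
thresholds:
  transitionHi: 1
  transitionLo: -1
  severityMild: 1
  severityStrong: 2.5
staging:
  mode: markers
ratio:
  denominator: chr9
scale_factor: 10000
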