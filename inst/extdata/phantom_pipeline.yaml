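# Baseline pipeline configuration for a DiceCT-scale phantom.
# Keys follow the cylinder-correlation / trace-correlation-lines
# nomenclature; lengths in micrometres, angles in degrees.
OuterCylinderRadius: 90
CylinderLength: 450
AngularSampling: 10
MaskCylinderRadius: 135
ErosionIterations: 1
MinimumSeedCorrelation: 0.2
MinimumContinuationQuality: 0.12
DirectionCoefficient: 0.5
MinimumDistance: 150
MinimumLength: 1000
MaximumStepAngle: 45
MaximumTotalBend: 90
SmoothWindow: 5
TendonAxis: "0,0,1"
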