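parameter,gender,side,mean,median,sd,min,max
depth_mm,male,left,39.74,40.00,2.91,31.27,46.15
depth_mm,male,right,39.83,40.29,3.07,31.24,46.53
depth_mm,female,left,37.41,37.33,2.67,29.45,46.06
depth_mm,female,right,37.27,37.30,2.65,29.26,45.44
volume_ml,male,left,28.95,29.61,3.63,17.37,38.43
volume_ml,male,right,29.02,29.40,3.63,17.91,36.85
volume_ml,female,left,25.39,25.13,3.14,17.36,35.29
volume_ml,female,right,25.48,25.19,3.25,17.90,36.78
area_mm2,male,left,3878.68,3952.46,395.61,2697.10,4648.56
area_mm2,male,right,3871.49,3898.07,382.11,2646.76,4793.88
area_mm2,female,left,3492.22,3465.58,339.04,2712.26,4523.00
area_mm2,female,right,3490.72,3494.79,336.55,2628.22,4448.10
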