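# Best-threshold (lowest Dissimilarity Index) statistics per stone-model
# case, transcribed from the published bench study's per-case results
# table: 10 dental stone casts, three CBCT acquisitions each
# (Planmeca Mid at 80 kVp, Planmeca Mid at 90 kVp, Newtom VG).
# Columns: device id, case number, best threshold (HU), 95% bound (mm),
# median deviation (mm), interquartile range (mm), Dissimilarity Index.
device,case,threshold,p95_mm,median_mm,iqr_mm,di
Planmeca80,1,2425,0.18,0.051,0.062,3.2
Planmeca80,2,2225,0.19,0.057,0.076,4.3
Planmeca80,3,2325,0.19,0.055,0.073,4.0
Planmeca80,4,2125,0.19,0.065,0.078,5.1
Planmeca80,5,2025,0.17,0.053,0.063,3.3
Planmeca80,6,2325,0.15,0.053,0.068,3.6
Planmeca80,7,1925,0.20,0.069,0.082,5.7
Planmeca80,8,2225,0.16,0.056,0.070,3.9
Planmeca80,9,2025,0.18,0.067,0.080,5.3
Planmeca80,10,1925,0.21,0.060,0.080,4.8
Planmeca90,1,2425,0.20,0.051,0.061,3.1
Planmeca90,2,2325,0.18,0.050,0.080,4.0
Planmeca90,3,2225,0.16,0.057,0.073,4.1
Planmeca90,4,2225,0.19,0.052,0.070,3.6
Planmeca90,5,2125,0.20,0.063,0.084,5.3
Planmeca90,6,2325,0.17,0.053,0.063,3.3
Planmeca90,7,2025,0.16,0.057,0.076,4.3
Planmeca90,8,2025,0.19,0.063,0.078,4.9
Planmeca90,9,1925,0.18,0.070,0.080,5.6
Planmeca90,10,1825,0.21,0.058,0.078,4.5
NewtomVG,1,2225,0.13,0.045,0.063,2.8
NewtomVG,2,2025,0.12,0.035,0.049,1.7
NewtomVG,3,1925,0.13,0.043,0.053,2.3
NewtomVG,4,2025,0.13,0.039,0.049,1.9
NewtomVG,5,1825,0.14,0.044,0.058,2.5
NewtomVG,6,2125,0.10,0.032,0.039,1.2
NewtomVG,7,2025,0.11,0.032,0.047,1.5
NewtomVG,8,1925,0.13,0.035,0.052,1.8
NewtomVG,9,1825,0.16,0.049,0.065,3.2
NewtomVG,10,1825,0.16,0.045,0.051,2.3
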