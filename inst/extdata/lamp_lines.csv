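species,wavelength_air_nm,relative_intensity
Hg/Ar,365.015,0.70
Hg/Ar,404.656,0.90
Hg/Ar,435.833,1.00
Hg/Ar,546.074,0.95
Hg/Ar,576.960,0.55
Hg/Ar,579.066,0.50
Hg/Ar,696.543,0.45
Hg/Ar,706.722,0.40
Hg/Ar,738.398,0.35
Hg/Ar,750.387,0.55
Hg/Ar,763.511,0.60
Hg/Ar,772.376,0.38
Hg/Ar,794.818,0.30
Hg/Ar,800.616,0.33
Hg/Ar,811.531,0.70
Hg/Ar,826.452,0.28
Hg/Ar,842.465,0.36
Hg/Ar,912.297,0.48
Hg/Ar,922.450,0.27
Hg/Ar,965.779,0.22
H,410.174,0.15
H,434.047,0.30
H,486.135,0.80
H,656.279,1.00
He,388.865,0.50
He,447.148,0.90
He,471.314,0.20
He,492.193,0.30
He,501.568,0.70
He,587.562,1.00
He,667.815,0.60
He,706.519,0.50
He,728.135,0.25
He,1083.030,0.40
Ne,540.056,0.30
Ne,585.249,1.00
Ne,588.190,0.50
Ne,594.483,0.45
Ne,597.553,0.28
Ne,602.999,0.35
Ne,607.434,0.50
Ne,609.616,0.60
Ne,614.306,0.70
Ne,616.359,0.40
Ne,621.728,0.34
Ne,626.650,0.48
Ne,633.443,0.55
Ne,638.299,0.75
Ne,640.225,0.90
Ne,650.653,0.70
Ne,653.288,0.40
Ne,659.895,0.52
Ne,667.828,0.44
Ne,671.704,0.36
Ne,692.947,0.42
Ne,703.241,0.65
Ne,717.394,0.29
Ne,724.517,0.46
Ne,743.890,0.37
Ne,748.887,0.24
Ne,753.577,0.31
Ne,837.761,0.32
Ne,849.536,0.37
Ne,865.438,0.31
Ne,878.062,0.26
Ne,885.387,0.21
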