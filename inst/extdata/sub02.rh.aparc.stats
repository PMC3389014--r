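# Table of FreeSurfer cortical parcellation anatomical statistics (synthetic example)
# subjectname sub02
# hemi rh
# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg ThickStd
entorhinal     583   401  1745.5  3.10  0.69
parsopercularis  2105  1422  4255.0  2.51  0.44
precentral     7298  4719 12188.4  2.44  0.50
superiorfrontal  9987  6521 20102.3  2.66  0.52
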