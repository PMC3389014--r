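# Table of FreeSurfer cortical parcellation anatomical statistics (synthetic example)
# subjectname sub01
# hemi lh
# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg ThickStd
entorhinal     610   420  1905.0  3.21  0.71
parsopercularis  2210  1501  4512.4  2.55  0.48
precentral     7410  4822 12933.8  2.48  0.53
superiorfrontal 10110  6650 21010.2  2.71  0.50
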