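# Title Automated segmentation statistics (synthetic example, not from MRI)
# subjectname sub02
# Measure EstimatedTotalIntraCranialVol, eTIV, Estimated Total Intracranial Volume, 1486742.0, mm^3
# Measure BrainSeg, BrainSegVol, Brain Segmentation Volume, 1180424.0, mm^3
# ColHeaders Index SegId NVoxels Volume_mm3 StructName normMean
  1   10  7523  7105.3  Left-Thalamus-Proper   88.1
  2   49  7610  7198.2  Right-Thalamus-Proper  87.4
  3   30    28    33.1  vessel                 61.0
  4   12  5110  4987.4  Left-Putamen           83.9
  5   51  5242  5101.9  Right-Putamen          84.2
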