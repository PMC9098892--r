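measure,unit,value
lesion_area_mm2,mm2,1.8
lesion_area_mm2,mm2,2.4
lesion_area_mm2,mm2,2.9
lesion_area_mm2,mm2,3.1
lesion_area_mm2,mm2,3.0
lesion_area_mm2,mm2,2.6
lesion_area_mm2,mm2,2.2
lesion_area_mm2,mm2,1.9
lesion_area_mm2,mm2,1.5
lesion_area_mm2,mm2,1.2
lesion_area_mm2,mm2,0.9
lesion_area_mm2,mm2,0.7
lesion_area_mm2,mm2,0.5
lesion_area_mm2,mm2,0.3
lesion_area_mm2,mm2,0.2
lesion_area_mm2,mm2,0.1
cortical_thickness_mm,mm,1.12
cortical_thickness_mm,mm,1.05
cortical_thickness_mm,mm,0.98
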