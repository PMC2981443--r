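taxon,element,a_out_mm,b_out_mm,cortical_thickness_mm,length_mm,mass_kg
synthetic_azhdarchid_A,humerus,20,16,3,240,20;22;25
synthetic_azhdarchid_A,femur,9,8.5,2,210,22
synthetic_azhdarchid_B,humerus,40,32,5,540,180;250
synthetic_small_form,humerus,6,5,1.5,90,2.5
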