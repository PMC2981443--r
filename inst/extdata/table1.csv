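taxon,common_name,group,span_m,mass_kg,area_m2,weight_N,aspect_ratio,wing_loading,reference
Pteranodon,,pterosaur,6.95,14.95,2.53,146.56,19.10,57.93,Brower & Veinus
Pteranodon,,pterosaur,6.95,16.6,4.62,162.85,10.455,35.248,Hazlehurst & Rayner
Pteranodon,,pterosaur,6.95,16.60,2.65,162.85,18.23,61.45,Chatterjee & Templin
Pteranodon,,pterosaur,5.43,36.68,1.60,359.84,18.42,224.79,Witton
Quetzalcoatlus,,pterosaur,10.39,70.00,9.55,686.70,11.30,71.91,Chatterjee & Templin
Quetzalcoatlus,,pterosaur,9.64,259.06,11.36,2541.40,8.18,223.66,Witton
Diomedea exulans,Wandering albatross,bird,3.46,8.16,0.66,80.05,18.00,120.71,Savile
Diomedea exulans,Wandering albatross,bird,3.03,8.73,0.61,85.64,15.03,140.17,Pennycuick
Diomedea irrorata,Waved albatross,bird,2.31,2.04,0.36,20.01,15.00,56.11,Savile
Thalassarche melanophrys,Black-browed albatross,bird,2.16,3.79,0.36,37.18,13.11,104.44,Pennycuick
Thalassarche chrysostoma,Grey-headed albatross,bird,2.18,3.79,0.35,37.18,13.50,105.62,Pennycuick
Phoebetria sp.,Sooty albatross,bird,2.18,2.84,0.34,27.86,14.06,82.43,Pennycuick
Macronectes sp.,Giant petrel,bird,1.99,5.19,0.33,50.91,11.96,153.82,Pennycuick
Procellaria aequinoctialis,White-chinned petrel,bird,1.40,1.37,0.17,13.44,11.60,79.52,Pennycuick
Fulmarus sp.,Fulmar,bird,1.13,0.82,0.12,8.00,10.30,64.48,Pennycuick
Puffinus pacificus,Wedge-tailed shearwater,bird,1.01,0.38,0.10,3.73,10.20,37.28,Hertel
Puffinus nativitatis,Christmas shearwater,bird,0.82,0.34,0.07,3.34,9.61,47.65,Hertel
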