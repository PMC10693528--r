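substance_id,moa_id,level,viability_mean_pct,viability_sd_pct
acifluorfen,peroxisome_proliferation,1,104.7,4.2
acifluorfen,peroxisome_proliferation,2,105.2,4.8
acifluorfen,peroxisome_proliferation,3,99.9,1.3
acifluorfen,peroxisome_proliferation,4,58.4,1.5
acifluorfen,peroxisome_proliferation,5,27.8,1.3
wy_14643,peroxisome_proliferation,1,100.9,3.8
wy_14643,peroxisome_proliferation,2,97.1,3.1
wy_14643,peroxisome_proliferation,3,94.6,1.8
wy_14643,peroxisome_proliferation,4,46.4,2.0
wy_14643,peroxisome_proliferation,5,23.2,1.1
beta_naphthoflavone,enzyme_induction,1,103.4,4.3
beta_naphthoflavone,enzyme_induction,2,113.8,3.7
beta_naphthoflavone,enzyme_induction,3,104.1,1.6
beta_naphthoflavone,enzyme_induction,4,34.5,3.4
beta_naphthoflavone,enzyme_induction,5,15.0,2.1
aroclor_1254,enzyme_induction,1,95.5,4.1
aroclor_1254,enzyme_induction,2,80.5,5.7
aroclor_1254,enzyme_induction,3,60.6,7.5
aroclor_1254,enzyme_induction,4,8.7,1.6
aroclor_1254,enzyme_induction,5,3.9,3.2
pendimethalin,enzyme_induction,1,98.3,3.9
pendimethalin,enzyme_induction,2,100.3,2.9
pendimethalin,enzyme_induction,3,82.4,4.9
pendimethalin,enzyme_induction,4,36.1,3.2
pendimethalin,enzyme_induction,5,18.5,3.2
ketoconazole,enzyme_inhibition,1,102.4,3.1
ketoconazole,enzyme_inhibition,2,102.0,0.9
ketoconazole,enzyme_inhibition,3,91.2,1.5
ketoconazole,enzyme_inhibition,4,64.7,1.5
ketoconazole,enzyme_inhibition,5,28.2,1.9
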