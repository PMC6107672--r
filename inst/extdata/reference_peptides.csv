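protein_accession,gene_name,description,sequence,lcms_neutral_mass,ims_mz_observed,score
REF_COL6A1,Col6a1,Collagen VI alpha 1,DRLLPPTQNNR,1322.70,1323.71,40
REF_COL6A1,Col6a1,Collagen VI alpha 1,VAVVQYSGQGQQQPGR,1700.86,1701.98,93
REF_COL6A1,Col6a1,Collagen VI alpha 1,LMQVEFGR,978.49,979.58,33
REF_COL6A1,Col6a1,Collagen VI alpha 1,SGDDVRGPSVVLK,1327.71,1328.64,34
REF_HSPA8,Hspa8,Heat shock cognate 71 kDa,DAGTIAGLNVLR,1198.67,1199.70,47
REF_HSPA8,Hspa8,Heat shock cognate 71 kDa,TTPSYVAFTDTER,1486.69,1487.82,63
REF_CA3,Ca3,Carbonic anhydrase 3,GGPLSGPYRLR,1171.64,1172.57,35
REF_CA3,Ca3,Carbonic anhydrase 3,SMLRGGPLSGPYR,1389.72,1390.75,40
REF_MYL3,Myl3,Myosin light chain 3,ALGQNPTQAEVLR,1395.75,1396.76,73
REF_MYL3,Myl3,Myosin light chain 3,AAPAPAAAPAAAPEPERPK,1781.94,1782.99,101
REF_FLNC,Flnc,Filamin C,LGSFGSITR,936.50,937.56,42
REF_FLNC,Flnc,Filamin C,GVAGVPAEFSIWTR,1488.77,1489.90,31
REF_TNC,Tnc,Tenascin-C,YAPISGGDHAEIDVPK,1667.81,1668.81,32
REF_TNC,Tnc,Tenascin-C,EGDPATINAATEIDAPR,1739.83,1740.95,32
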