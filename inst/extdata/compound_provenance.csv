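compound,field,value,units,source
tacrolimus,molecular_weight,804.02,g/mol,PubChem CID 445643
tacrolimus,fu_plasma,0.01,fraction,"Literature consensus ~1% unbound in plasma (Venkataramanan et al. 1995, Clin Pharmacokinet)"
tacrolimus,bp_ratio_ref,15,ratio,"Whole-blood/plasma ratio ~15 at normal hematocrit and therapeutic concentrations (Jusko et al. 1995)"
tacrolimus,hct_ref,0.45,fraction,Package reference hematocrit
tacrolimus,fa,0.66,fraction,"Calibrated so the population geometric-mean oral bioavailability in healthy volunteers is ~0.235 (literature capsule bioavailability ~20-25%), given the gut/hepatic extraction below"
tacrolimus,ka,0.7,1/h,"Calibrated to capsule tmax of 1.5-3 h (Prograf label) and to steady-state peak-to-trough fluctuation at 12-h dosing"
tacrolimus,fu_gut,1,fraction,Default for lipophilic CYP3A substrates without enterocyte binding data
tacrolimus,clint_cyp3a4_liver,3040,L/h at reference abundance,"Well-stirred inversion of a whole-blood hepatic clearance of 2.0 L/h in CYP3A5 non-expressors (literature blood CL ~0.03 L/h/kg) at Qh = 87 L/h, fu_blood = 6.67e-4"
tacrolimus,clint_cyp3a5_liver,4762,L/h at reference abundance,"Well-stirred inversion of a whole-blood hepatic clearance of 4.9 L/h in CYP3A5 expressors (~2.5-fold the non-expressor clearance, consistent with CYP3A5*1 pharmacogenetic studies)"
tacrolimus,clint_cyp3a4_gut,25.5,L/h,"Qgut-model inversion of an intestinal availability Fg ~0.41 in CYP3A5 non-expressors (Fg 0.3-0.6 reported for tacrolimus) at Qent = 18 L/h"
tacrolimus,clint_cyp3a5_gut,25.8,L/h,"Qgut-model inversion of the ~0.63-fold lower Fg in intestinal CYP3A5 expressors"
tacrolimus,cl_renal,0,L/h,"<1% of tacrolimus is renally cleared (Venkataramanan et al. 1995)"
tacrolimus,vss,1.3,L/kg,"Whole-blood steady-state volume ~1-1.5 L/kg (Venkataramanan et al. 1995)"
tacrolimus,k12,2,1/h,Calibrated distribution kinetics reproducing steady-state peak-to-trough fluctuation of twice-daily capsules in whole blood
tacrolimus,k21,0.12,1/h,Calibrated with k12 (terminal half-life ~35 h)
itraconazole,molecular_weight,705.64,g/mol,PubChem CID 55283
itraconazole,fu_plasma,0.002,fraction,"99.8% plasma protein binding (Sporanox label)"
itraconazole,bp_ratio_ref,0.58,ratio,"Blood/plasma ratio 0.58 (Sporanox label)"
itraconazole,hct_ref,0.45,fraction,Package reference hematocrit
itraconazole,fa,1,fraction,Fasted oral solution; complete release assumed
itraconazole,ka,0.5,1/h,"Oral-solution tmax ~2.5 h (Barone et al. 1998)"
itraconazole,fu_gut,1,fraction,Default without enterocyte binding data
itraconazole,clint_cyp3a4_liver,8029,L/h at reference abundance,"Well-stirred inversion of a whole-blood clearance of 21 L/h (oral-solution CL/F ~38 L/h with F ~0.55)"
itraconazole,clint_cyp3a5_liver,0,L/h,Itraconazole is a CYP3A4 substrate; no CYP3A5 clearance assigned
itraconazole,clint_cyp3a4_gut,6.83,L/h,"Qgut-model inversion of oral-solution Fg ~0.73, consistent with F ~0.55 and Fh ~0.76"
itraconazole,clint_cyp3a5_gut,0,L/h,No CYP3A5 clearance assigned
itraconazole,cl_renal,0,L/h,"Negligible renal elimination of parent drug (Sporanox label)"
itraconazole,vss,13,L/kg,"Blood-referenced volume giving the reported terminal half-life of 30-40 h at CL 21 L/h"
itraconazole,k12,0.3,1/h,Moderate peripheral distribution (lipophilic azole)
itraconazole,k21,0.15,1/h,Paired with k12
itraconazole,ki_cyp3a4,6,ng/mL unbound,"In-vitro competitive Ki values for itraconazole span ~2-270 nM; 6 ng/mL (8.5 nM) unbound adopted within that range so that simulated steady-state unbound exposure at 200 mg daily reproduces the reported 2-3 fold tacrolimus AUC increase"
itraconazole,ki_cyp3a5,6,ng/mL unbound,Set equal to the CYP3A4 value; the CYP3A5 inhibitory potency of itraconazole is assumed equipotent
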