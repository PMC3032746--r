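# fmoscore CDK2 inhibitor reference set, format v1
# 28 cyclin-dependent kinase 2 inhibitors: IC50 (micromolar), train/test role,
# the four scoring-function descriptors (dH_gas = sum of ligand-residue FMO pair
# interaction energies; dG_psolv = Poisson-Boltzmann polar solvation; dG_npsolv =
# gamma*SASA+b nonpolar solvation; TdS = rotatable-bond entropy penalty; all
# kcal/mol), the IC50-derived experimental binding free energy, the reference
# PLS model's reported prediction, and the reported residual (expt - predicted).
# The two free-energy columns of the original compilation carry interchanged
# headers; the assignment stored here is fixed by the identities
# residual_reported = dG_experimental - dG_predicted_reported and
# dG_experimental = RT ln IC50[mol/L] at 310 K, which hold for every row.
# Entries marked modelled=yes have no crystal structure of their own; pdb_code
# is the template complex used to model them and resolution is left blank.
# md5 2a9d361a1010e4219a6b3e8318c5e7af
entry,pdb_code,modelled,resolution,ic50_uM,role,dH_gas,dG_psolv,dG_npsolv,TdS,dG_experimental,dG_predicted_reported,residual_reported
1,2VTA,no,2.00,185.000,train,-41.712,-8.756,-2.296,0,-5.292,-4.276,-1.016
2,2VTH,no,1.90,120.000,train,-65.593,-16.745,-2.782,1,-5.558,-5.852,0.294
3,2VTM,no,2.25,1000.000,train,-51.706,-9.542,-2.434,1,-4.253,-5.167,0.915
4,2VTJ,yes,,7.000,test,-43.071,-8.427,-2.852,2,-7.308,-6.242,-1.066
5,2VTJ,no,2.20,1.900,train,-81.351,-20.047,-3.196,3,-8.110,-7.751,-0.359
6,2VTR,no,1.90,1.500,train,-55.993,-11.678,-3.085,3,-8.256,-7.291,-0.965
7,2VTS,no,1.90,0.030,train,-157.304,-59.945,-3.837,5,-10.665,-10.268,-0.397
8,2VTN,yes,,3.000,test,-27.615,-15.471,-3.098,3,-7.829,-6.693,-1.136
9,2VTI,no,2.00,0.660,train,-93.407,-25.109,-3.490,4,-8.761,-8.845,0.083
10,2VTL,no,2.00,97.000,train,-56.084,-13.070,-2.791,3,-5.689,-6.751,1.062
11,2VTN,yes,,25.000,test,-58.015,-20.047,-2.762,1,-6.524,-5.595,-0.929
12,2VTN,yes,,85.000,test,-63.864,-12.846,-2.906,3,-5.770,-7.099,1.329
13,2VTN,no,2.20,0.850,train,-61.236,-14.824,-3.221,5,-8.606,-8.518,-0.087
14,2VTP,yes,,0.730,test,-60.888,-15.442,-3.292,6,-8.699,-9.105,0.406
15,2VTT,yes,,1.600,test,-60.917,-15.604,-3.709,7,-8.216,-10.308,2.091
16,2VTT,yes,,0.090,test,-60.720,-13.072,-3.750,6,-9.988,-9.951,-0.037
17,2VTO,no,2.19,0.140,train,-64.809,-17.109,-3.682,6,-9.716,-9.811,0.095
18,2VTP,no,2.15,0.003,train,-177.695,-16.106,-3.727,6,-12.082,-12.015,-0.067
19,2VTT,yes,,0.025,test,-70.768,-15.895,-3.535,7,-10.777,-10.183,-0.593
20,2VTT,yes,,0.012,test,-71.985,-14.962,-3.781,6,-11.229,-10.169,-1.059
21,2VTT,yes,,0.019,test,-79.530,-19.304,-3.846,6,-10.946,-10.316,-0.630
22,2VTT,yes,,0.038,test,-81.814,-58.172,-3.927,6,-10.519,-9.547,-0.972
23,2VTQ,no,1.90,0.140,train,-106.410,-54.144,-3.794,6,-9.716,-9.873,0.157
24,2VTT,no,1.68,0.044,train,-138.056,-52.223,-3.803,6,-10.429,-10.524,0.095
25,2VTT,yes,,0.910,test,-94.987,-51.774,-3.824,6,-8.564,-9.771,1.207
26,2VTT,yes,,0.052,test,-100.764,-54.605,-3.764,7,-10.326,-10.190,-0.136
27,2VTT,yes,,0.063,test,-96.554,-53.308,-3.797,6,-10.208,-9.716,-0.491
28,2VU3,no,1.85,0.082,train,-112.339,-53.340,-3.929,6,-10.045,-10.236,0.191
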