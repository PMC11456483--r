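heterogeneity:
  delta_e: 0.3
  delta_i: 0.02
  i_back_e: 0.106666666666667
perturbation: none
populations:
  L2/3E: 10341.0
  L2/3I: 2917.0
  L4E: 10957.0
  L4I: 2739.0
  L5E: 2425.0
  L5I: 532.0
  L6E: 7197.0
  L6I: 1474.0
pathways:
  p_intra:
    L2/3E->L2/3E: 0.1184
    L2/3E->L2/3I: 0.1008
    L2/3E->L4E: 0.0077
    L2/3E->L4I: 0.0691
    L2/3E->L5E: 0.1017
    L2/3E->L5I: 0.0436
    L2/3E->L6E: 0.0156
    L2/3E->L6I: 0.0364
    L2/3I->L2/3E: 0.1552
    L2/3I->L2/3I: 0.1371
    L2/3I->L4E: 0.0059
    L2/3I->L4I: 0.0029
    L2/3I->L5E: 0.0622
    L2/3I->L5I: 0.0269
    L2/3I->L6E: 0.0066
    L2/3I->L6I: 0.001
    L4E->L2/3E: 0.0846
    L4E->L2/3I: 0.0363
    L4E->L4E: 0.0519
    L4E->L4I: 0.1093
    L4E->L5E: 0.0411
    L4E->L5I: 0.0209
    L4E->L6E: 0.0211
    L4E->L6I: 0.0034
    L4I->L2/3E: 0.0629
    L4I->L2/3I: 0.0515
    L4I->L4E: 0.1453
    L4I->L4I: 0.1597
    L4I->L5E: 0.0057
    L4I->L5I: 0.0022
    L4I->L6E: 0.0166
    L4I->L6I: 0.0005
    L5E->L2/3E: 0.0323
    L5E->L2/3I: 0.0755
    L5E->L4E: 0.0067
    L5E->L4I: 0.0033
    L5E->L5E: 0.0758
    L5E->L5I: 0.0566
    L5E->L6E: 0.0572
    L5E->L6I: 0.0277
    L5I->L4E: 0.0003
    L5I->L5E: 0.3765
    L5I->L5I: 0.3158
    L5I->L6E: 0.0197
    L5I->L6I: 0.008
    L6E->L2/3E: 0.0076
    L6E->L2/3I: 0.0042
    L6E->L4E: 0.0453
    L6E->L4I: 0.1057
    L6E->L5E: 0.0204
    L6E->L5I: 0.0086
    L6E->L6E: 0.0401
    L6E->L6I: 0.0658
    L6I->L6E: 0.2252
    L6I->L6I: 0.1443
  g_peak:
    E->E: 0.004069
    I->E: 0.02672
    E->I: 0.003276
    I->I: 0.02138
  p_inter: 0.1
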