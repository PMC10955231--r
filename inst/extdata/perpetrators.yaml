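CTC:
  id: CTC
  mw_g_mol: 747.95
  dose_mg: 500.0
  n_doses: 10.0
  interval_h: 12.0
  start_h: 0.0
  ka_h: 0.5
  v_f_l: 250.0
  cl_f_l_h: 40.0
  fu_plasma: 0.3
  bp_ratio: 1.0
  interactions:
  - target: CYP3A
    organ: both
    mechanism: mbi
    ki_u: ~
    kinact: 2.0
    ki_app_u: 15.0
  - target: CYP3A
    organ: both
    mechanism: competitive
    ki_u: 16.0
    kinact: ~
    ki_app_u: ~
  - target: P-gp
    organ: gut
    mechanism: competitive
    ki_u: 35.0
    kinact: ~
    ki_app_u: ~
  metabolite: ~
ITZ:
  id: ITZ
  mw_g_mol: 705.63
  dose_mg: 200.0
  n_doses: 5.0
  interval_h: 24.0
  start_h: 0.0
  ka_h: 0.4
  v_f_l: 700.0
  cl_f_l_h: 22.0
  fu_plasma: 0.036
  bp_ratio: 1.0
  interactions:
  - target: CYP3A
    organ: both
    mechanism: competitive
    ki_u: 0.04
    kinact: ~
    ki_app_u: ~
  - target: P-gp
    organ: gut
    mechanism: competitive
    ki_u: 2.0
    kinact: ~
    ki_app_u: ~
  metabolite:
    id: OH-ITZ
    conc_ratio: 1.0
    interactions:
    - target: CYP3A
      organ: both
      mechanism: competitive
      ki_u: 0.08
      kinact: ~
      ki_app_u: ~
    - target: P-gp
      organ: gut
      mechanism: competitive
      ki_u: 5.0
      kinact: ~
      ki_app_u: ~
VP:
  id: VP
  mw_g_mol: 454.6
  dose_mg: 120.0
  n_doses: 1.0
  interval_h: 24.0
  start_h: 0.0
  ka_h: 1.5
  v_f_l: 300.0
  cl_f_l_h: 50.0
  fu_plasma: 0.1
  bp_ratio: 0.84
  interactions:
  - target: CYP3A
    organ: both
    mechanism: mbi
    ki_u: ~
    kinact: 3.0
    ki_app_u: 3.0
  - target: P-gp
    organ: gut
    mechanism: competitive
    ki_u: 0.1
    kinact: ~
    ki_app_u: ~
  metabolite: ~
RF:
  id: RF
  mw_g_mol: 822.94
  dose_mg: 600.0
  n_doses: 1.0
  interval_h: 24.0
  start_h: 0.0
  ka_h: 1.0
  v_f_l: 60.0
  cl_f_l_h: 12.0
  fu_plasma: 0.2
  bp_ratio: 1.0
  interactions:
  - target: P-gp
    organ: gut
    mechanism: competitive
    ki_u: 1.5
    kinact: ~
    ki_app_u: ~
  - target: CYP3A
    organ: both
    mechanism: competitive
    ki_u: 6.0
    kinact: ~
    ki_app_u: ~
  metabolite: ~
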