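DABE:
  id: DABE
  mw_g_mol: 627.73
  binding:
    fu_plasma: 0.05
    bp_ratio: 1.0
    fu_gut: 1.0
  peff_1e4_cm_s: 4.0
  vss_l_kg: 3.0
  central_fraction: 0.4
  q_l_h: 10.0
  renal_cl_u_l_h: 0.0
  other_cl_u_l_h: 0.0
  plasma_t_half_min: 364.0
  plasma_product: BIBR1087
  bl_scalar: 1.0
  gut_pathways:
  - enzyme: CES2
    organ: gut
    vmax: 5000.0
    km_u: 50.0
    isef: 1.0
    fu_inc: 1.0
    product: BIBR0951
    source: organ
    is_cyp: no
  - enzyme: CES2
    organ: gut
    vmax: 350.0
    km_u: 50.0
    isef: 1.0
    fu_inc: 1.0
    product: BIBR1087
    source: organ
    is_cyp: no
  - enzyme: CYP3A4
    organ: gut
    vmax: 30.0
    km_u: 2.0
    isef: 1.0
    fu_inc: 1.0
    product: oxidative_sink
    source: organ
    is_cyp: yes
  liver_pathways: []
  bile_clint_ul_min_1e6: 0.0
  pgp:
    transporter: P-gp
    location: gut_apical
    jmax: 150.0
    km_um: 2.6
  solubility_mg_ml: 0.003
  solubility_stomach_mg_ml: 1.0
  csr: 17.9
  prc_h: 2.88
  density_g_ml: 1.2
  particle_radius_um: 10.0
BIBR0951:
  id: BIBR0951
  mw_g_mol: 499.57
  binding:
    fu_plasma: 0.227
    bp_ratio: 0.6
    fu_gut: 1.0
  peff_1e4_cm_s: 0.1297179
  vss_l_kg: 1.5
  central_fraction: 0.5
  q_l_h: 5.0
  renal_cl_u_l_h: 0.0
  other_cl_u_l_h: 0.0
  plasma_t_half_min: 55.0
  plasma_product: DAB
  bl_scalar: 0.1
  gut_pathways:
  - enzyme: CYP3A4
    organ: gut
    vmax: 30.0
    km_u: 2.0
    isef: 1.0
    fu_inc: 1.0
    product: oxidative_sink
    source: organ
    is_cyp: yes
  liver_pathways:
  - enzyme: CES1
    organ: liver
    vmax: 50000.0
    km_u: 50.0
    isef: 1.0
    fu_inc: 1.0
    product: DAB
    source: per_mg
    is_cyp: no
  - enzyme: CYP3A4
    organ: liver
    vmax: 556.0
    km_u: 2.0
    isef: 1.0
    fu_inc: 1.0
    product: oxidative_sink
    source: per_mg
    is_cyp: yes
  bile_clint_ul_min_1e6: 273.0
  pgp: ~
  solubility_mg_ml: .na.real
  solubility_stomach_mg_ml: .na.real
  csr: 1.0
  prc_h: 0.0
  density_g_ml: 1.2
  particle_radius_um: 10.0
BIBR1087:
  id: BIBR1087
  mw_g_mol: 599.68
  binding:
    fu_plasma: 0.018
    bp_ratio: 0.6
    fu_gut: 1.0
  peff_1e4_cm_s: 0.2
  vss_l_kg: 2.0
  central_fraction: 0.5
  q_l_h: 5.0
  renal_cl_u_l_h: 0.0
  other_cl_u_l_h: 6000.0
  plasma_t_half_min: .na.real
  plasma_product: .na.character
  bl_scalar: 1.0
  gut_pathways: []
  liver_pathways:
  - enzyme: CES1
    organ: liver
    vmax: 500.0
    km_u: 50.0
    isef: 1.0
    fu_inc: 1.0
    product: DAB
    source: per_mg
    is_cyp: no
  - enzyme: CES2
    organ: liver
    vmax: 250.0
    km_u: 50.0
    isef: 1.0
    fu_inc: 1.0
    product: DAB
    source: per_mg
    is_cyp: no
  bile_clint_ul_min_1e6: 0.0
  pgp: ~
  solubility_mg_ml: .na.real
  solubility_stomach_mg_ml: .na.real
  csr: 1.0
  prc_h: 0.0
  density_g_ml: 1.2
  particle_radius_um: 10.0
DAB:
  id: DAB
  mw_g_mol: 471.51
  binding:
    fu_plasma: 0.65
    bp_ratio: 0.9
    fu_gut: 1.0
  peff_1e4_cm_s: 0.0
  vss_l_kg: 1.0
  central_fraction: 0.35
  q_l_h: 12.0
  renal_cl_u_l_h: 8.0
  other_cl_u_l_h: 2.0
  plasma_t_half_min: .na.real
  plasma_product: .na.character
  bl_scalar: 1.0
  gut_pathways: []
  liver_pathways: []
  bile_clint_ul_min_1e6: 0.0
  pgp: ~
  solubility_mg_ml: .na.real
  solubility_stomach_mg_ml: .na.real
  csr: 1.0
  prc_h: 0.0
  density_g_ml: 1.2
  particle_radius_um: 10.0
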