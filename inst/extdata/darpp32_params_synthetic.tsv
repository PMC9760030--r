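# Synthetic rate table for the packaged DARPP-32 reconstruction.
# Stochastic units for a 1e-15 L reaction volume (1 uM ~ 602 copies):
# bimolecular constants are per-pair per second (1e6 /M/s ~ 1.66e-3),
# unimolecular per second. Values are order-of-magnitude placeholders with
# weak (micromolar) binding affinities; they are NOT fitted constants of
# the source reaction system, which are not published with the network.
rate_id	value	note
pka_d_bind	1.7e-3	C + D(Thr34-u) association, ~1e6 /M/s
pka_d_unbind	4	weak binding, Kd ~ 2 uM
pka_d_cat	3	Thr34 phosphorylation
pka_inh_bind	1.7e-3	C sequestration by Thr75-p DARPP-32
pka_inh_unbind	0.7	tighter pseudosubstrate binding
cdk5_d_bind	1.7e-3	CDK5 + D(Thr75-u)
cdk5_d_unbind	6	weak
cdk5_d_cat	2	Thr75 phosphorylation
ck1_d_bind	1.7e-3	CK1(active) + D(Ser137-u)
ck1_d_unbind	6	weak
ck1_d_cat	2	Ser137 phosphorylation (zeroed by Ser137Ala)
pp2b_d_bind	1.7e-3	active PP2B + D(Thr34-p, Ser137-u)
pp2b_d_unbind	4	weak
pp2b_d_cat	5	Thr34 dephosphorylation
pp2ap_d_bind	1.7e-3	phospho-PP2A + D(Thr75-p)
pp2ap_d_unbind	5	weak
pp2ap_d_cat	4	Thr75 dephosphorylation
pp2aca_d_bind	1.7e-3	Ca-PP2A + D(Thr75-p)
pp2aca_d_unbind	5	weak
pp2aca_d_cat	4	Thr75 dephosphorylation
pp2c_d_bind	1.7e-3	PP2C + D(Ser137-p)
pp2c_d_unbind	5	weak
pp2c_d_cat	3	Ser137 dephosphorylation (zeroed by constSer137)
ck1_auto	0.2	CK1 autophosphorylation (inactivation)
pp2b_ck1_bind	1.7e-3	active PP2B + phospho-CK1
pp2b_ck1_unbind	4	weak
pp2b_ck1_cat	4	CK1 reactivation
pka_pde_bind	1.7e-3	C + PDE(u)
pka_pde_unbind	4	weak
pka_pde_cat	3	PDE activation
pde_auto_dephos	0.1	PDE relaxation
pka_pp2a_bind	1.7e-3	C + PP2A(u)
pka_pp2a_unbind	4	weak
pka_pp2a_cat	3	PP2A activation by PKA
pp2a_auto_dephos	0.1	PP2A relaxation
PP2B_k1f	2.8e-3	first Ca pair on PP2B (per pair of ions)
PP2B_k1r	1	inactive <- half-active
PP2B_k2f	2.8e-3	second Ca pair
PP2B_k2r	0.5	half-active <- active
R2C2_k1f	1.7e-3	first cAMP pair on R2C2
R2C2_k1r	2	weak
R2C2_k2f	1.7e-3	second cAMP pair
R2C2_k2r	1	weak
pka_release	8	C release from cAMP-saturated holoenzyme
pka_rebind	1.7e-3	holoenzyme reformation
camp_synth	0.5	basal adenylyl-cyclase production, copies/s
camp_deg_basal	0.05	basal cAMP turnover
pde_camp_bind	1.7e-3	PDE + cAMP
pde_camp_unbind	4	weak
pde_camp_deg_u	0.5	basal PDE hydrolysis
pde_camp_deg_p	10	phospho-PDE hydrolysis
ca_influx	0.5	basal Ca leak, copies/s
ca_efflux	2	Ca clearance (pumps/exchangers)
pp2a_ca_bind	1.7e-3	Ca + PP2A
pp2a_ca_unbind	2	weak
init_D	6022	10 uM DARPP-32
init_R2C2	602	1 uM PKA holoenzyme
init_PP2B	602	1 uM calcineurin
init_PP2A	602	1 uM
init_PP2C	602	1 uM
init_CK1	301	0.5 uM
init_CDK5	301	0.5 uM
init_PDE	1204	2 uM
stim_camp_time	100	s; cAMP pulse
stim_camp_copies	6022	10 uM pulse
stim_ca_start	300	s; first Ca spike
stim_ca_interval	10	s between spikes
stim_ca_copies	1204	2 uM per spike
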