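# Default kinetic and sensor parameters for the glucose dynamics simulator.
#
# Shared rates are calibrated so that wild-type (nonTg) defaults give a
# relative-ratio slope of about -2 %/min in the 2-7 min window after a
# 2.5 -> 0.2 mM glucose restriction and about +10% at 50 min of a
# 2.5 -> 10 mM step. Calibration values are defaults, not claims.
#
# Units: fluxes mM/min, affinities mM, time constants min.
kinetics:
  v_transport: 0.038        # facilitative carrier Vmax (GluT1/GluT3 lumped)
  k_transport: 0.64         # carrier half-saturation
  v_glycolysis: 0.0126      # resting glycolytic flux (HK1 -> G3PDH branch)
  v_ppp: 0.0126             # resting pentose phosphate flux (G6PDH branch)
  v_hbp_max: 0.02           # peak transient hexosamine flux under IAA
  k_consume: 0.026          # hexokinase half-saturation for consumption
  tau_hk_inhibition: 10     # G6P build-up shutting hexokinase under IAA
  tau_hbp_transient: 6      # decay of the transient hexosamine flux
genotypes:
  nonTg:
    glycolysis_scale: 1.0
    ppp_scale: 1.0
    hbp_transient_scale: 0.0
  3xTgAD:
    glycolysis_scale: 1.4   # higher glycolytic activity
    ppp_scale: 0.3          # hampered pentose phosphate pathway
    hbp_transient_scale: 1.0 # transient hexosamine flux disclosed by IAA
sensor:
  k_d: 0.7                  # half-saturation of the ratio response, mM
  r_min: 0.70               # ratio at zero glucose (arbitrary positive)
  r_max: 1.70               # ratio at saturation (arbitrary positive)
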