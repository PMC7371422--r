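# Column-alias template for ingesting externally deposited behavioural
# tables with read_behaviour(path, aliases = <this file>).
# Each entry maps a canonical column name (left) to the column name used
# in the deposited file (right).  Edit the right-hand side to match the
# data set being loaded; entries whose right-hand column is absent are
# ignored.
trial_type: TrialType
choice: Chosen
ev_hv: HV
ev_lv: LV
ev_d: D
rt: RT
mag_hv: MagHV
prob_hv: ProbHV
mag_lv: MagLV
prob_lv: ProbLV
mag_d: MagD
prob_d: ProbD
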