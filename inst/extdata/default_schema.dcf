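name: pcq_total
vtype: ordinal
lo: 0
hi: 36
role: outcome
source: PCQ negative
group: outcome

name: pcq_emotional
vtype: ordinal
lo: 0
hi: 15
role: outcome
source: PCQ negative
group: outcome

name: pcq_physical
vtype: ordinal
lo: 0
hi: 12
role: outcome
source: PCQ negative
group: outcome

name: pcq_social
vtype: ordinal
lo: 0
hi: 9
role: outcome
source: PCQ negative
group: outcome

name: koko_critical
vtype: continuous
lo: 0
hi: 100
role: predictor
source: KoKo
group: health

name: koko_active
vtype: continuous
lo: 0
hi: 100
role: predictor
source: KoKo
group: health

name: help_apply
vtype: continuous
lo: 1
hi: 5
role: predictor
source: HELP
group: health

name: help_interact
vtype: continuous
lo: 1
hi: 5
role: predictor
source: HELP
group: health

name: komo_count
vtype: ordinal
lo: 0
hi: 12
role: predictor
source: KOMO
group: health

name: komo_severity
vtype: continuous
lo: 0
hi: 10
role: predictor
source: KOMO
group: health

name: zap_trust_gp
vtype: ordinal
lo: 1
hi: 4
role: predictor
source: ZAP item
group: screening

name: zap_quality
vtype: ordinal
lo: 1
hi: 4
role: predictor
source: ZAP item
group: screening

name: zap_satisfaction
vtype: ordinal
lo: 1
hi: 4
role: predictor
source: ZAP item
group: screening

name: osss3
vtype: ordinal
lo: 1
hi: 3
role: predictor
source: OSSS-3
group: sociodemographic

name: macarthur
vtype: ordinal
lo: 1
hi: 10
role: predictor
source: MacArthur Scale
group: sociodemographic

name: screen_positive
vtype: binary
lo: 0
hi: 1
role: predictor
source: administrative
group: screening

name: info_screening
vtype: ordinal
lo: 1
hi: 5
role: predictor
source: self-developed
group: screening

name: info_risk
vtype: ordinal
lo: 1
hi: 5
role: predictor
source: self-developed
group: screening

name: good_hands_gp
vtype: ordinal
lo: 1
hi: 5
role: predictor
source: self-developed
group: screening

name: household_size
vtype: ordinal
lo: 1
hi: 7
role: predictor
source: ISSP item
group: sociodemographic

name: edu_school
vtype: ordinal
lo: 1
hi: 5
role: predictor
source: ISSP item
group: sociodemographic

name: edu_professional
vtype: ordinal
lo: 1
hi: 4
role: predictor
source: ISSP item
group: sociodemographic

name: employed
vtype: binary
lo: 0
hi: 1
role: predictor
source: ISSP item
group: sociodemographic

name: life_partner
vtype: binary
lo: 0
hi: 1
role: predictor
source: ISSP item
group: sociodemographic

name: received_result
vtype: binary
lo: 0
hi: 1
role: predictor
source: self-developed
group: screening

name: future_participation
vtype: binary
lo: 0
hi: 1
role: predictor
source: self-developed
group: screening

name: sex
vtype: binary
lo: 0
hi: 1
role: predictor
source: ISSP item
group: sociodemographic

name: age
vtype: continuous
lo: 31
hi: 98
role: predictor
source: ISSP item
group: sociodemographic
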