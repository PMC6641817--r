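# Current-care parameterization: preterm neonatal mortality, sub-Saharan
# Africa, 2015. All coverage values are percent (units key below).
#
# Assumptions that are not printed numbers but modelling defaults:
#   * baseline referral-transfer probabilities are 0 (no routine transfer of
#     diagnosed cases under current care); scenario transforms raise them.
#   * the birth_asphyxia diagnostic gate (clinical recognition of asphyxia /
#     need for postresuscitation care) reuses the respiratory-distress
#     clinical-recognition profile; no separate asphyxia row is published.
name: baseline_ssa_2015
units: percent
coverage_cap: 98
anc_weighting: anc           # antenatal-timing profiles weight by ANC mix
incremental_mode: additive   # "+20%" scale-up read as +20 percentage points
population:
  n_preterm_births: 3988000
  delivery_mix: {home: 50, clinic: 35, hospital: 15}
  anc_mix: {home: 30, clinic: 65, hospital: 5}
subconditions:
  # prevalence | case-fatality rate absent any preventive or treatment
  # intervention; prevalences partition the cohort (sum to 100)
  - {name: RDS,            prevalence: 20, untreated_cfr: 35}
  - {name: IVH,            prevalence: 7,  untreated_cfr: 7.5}
  - {name: NEC,            prevalence: 1,  untreated_cfr: 25}
  - {name: sepsis,         prevalence: 9,  untreated_cfr: 40}
  - {name: birth_asphyxia, prevalence: 20, untreated_cfr: 20}
  - {name: LBW_only,       prevalence: 43, untreated_cfr: 2.1}
diagnostics:
  # penetration | utilization | efficacy, each per home/clinic/hospital
  - gate: preterm_labor
    penetration: {home: 50, clinic: 85, hospital: 90}
    utilization: {home: 5,  clinic: 20, hospital: 35}
    efficacy:    {home: 25, clinic: 80, hospital: 80}
  - gate: RDS
    penetration: {home: 50, clinic: 85, hospital: 90}
    utilization: {home: 40, clinic: 60, hospital: 95}
    efficacy:    {home: 75, clinic: 95, hospital: 95}
  - gate: IVH
    penetration: {home: 50, clinic: 85, hospital: 90}
    utilization: {home: 5,  clinic: 40, hospital: 70}
    efficacy:    {home: 25, clinic: 45, hospital: 45}
  - gate: NEC
    penetration: {home: 50, clinic: 85, hospital: 90}
    utilization: {home: 5,  clinic: 40, hospital: 70}
    efficacy:    {home: 25, clinic: 85, hospital: 85}
  - gate: sepsis
    penetration: {home: 95, clinic: 85, hospital: 90}
    utilization: {home: 75, clinic: 80, hospital: 90}
    efficacy:    {home: 75, clinic: 95, hospital: 95}
  - gate: LBW
    penetration: {home: 50, clinic: 85, hospital: 90}
    utilization: {home: 5,  clinic: 75, hospital: 90}
    efficacy:    {home: 25, clinic: 95, hospital: 95}
  - gate: birth_asphyxia   # assumption: RDS-style clinical recognition
    penetration: {home: 50, clinic: 85, hospital: 90}
    utilization: {home: 40, clinic: 60, hospital: 95}
    efficacy:    {home: 75, clinic: 95, hospital: 95}
interventions:
  - name: antenatal_corticosteroids
    role: preventive
    timing: antenatal
    requires_diagnosis: true
    gate: preterm_labor
    penetration: {home: 0, clinic: 10, hospital: 50}
    utilization: {home: 0, clinic: 5,  hospital: 25}
    efficacy: {RDS: 50, IVH: 42, NEC: 54}
  - name: cord_care        # chlorhexidine at home births, dry cord care in facilities
    role: preventive
    timing: postnatal
    requires_diagnosis: false
    penetration: {home: 0, clinic: 0, hospital: 0}
    utilization: {home: 0, clinic: 0, hospital: 0}
    efficacy: {sepsis: 55}
  - name: kangaroo_mother_care   # thermal care for stable LBW neonates; ungated
    role: treatment
    timing: postnatal
    requires_diagnosis: false
    penetration: {home: 95, clinic: 95, hospital: 95}
    utilization: {home: 0,  clinic: 0,  hospital: 2}
    efficacy: {LBW_only: 51}
  - name: warmers_incubators     # thermo-neutral environment when KMC not possible
    role: treatment
    timing: postnatal
    requires_diagnosis: true
    gate: target                 # LBW recognition
    penetration: {home: 0, clinic: 0, hospital: 50}
    utilization: {home: 0, clinic: 0, hospital: 30}
    efficacy: {LBW_only: 60}
  - name: breastfeeding          # mother's own milk; universal newborn care
    role: preventive
    timing: postnatal
    requires_diagnosis: false
    penetration: {home: 99, clinic: 99, hospital: 99}
    utilization: {home: 20, clinic: 40, hospital: 55}
    efficacy: {sepsis: 55, LBW_only: 18}
  - name: drying_stimulation     # immediate drying and additional stimulation at birth
    role: treatment
    timing: delivery
    requires_diagnosis: false
    penetration: {home: 50, clinic: 85, hospital: 90}
    utilization: {home: 50, clinic: 70, hospital: 85}
    efficacy: {birth_asphyxia: 15}
  - name: ppv                    # positive pressure ventilation with air
    role: treatment
    timing: delivery
    requires_diagnosis: true
    gate: target
    penetration: {home: 5,  clinic: 50, hospital: 95}
    utilization: {home: 20, clinic: 40, hospital: 60}
    efficacy: {birth_asphyxia: 40}
  - name: oxygen_therapy
    role: treatment
    timing: postnatal
    requires_diagnosis: true
    gate: target
    penetration: {home: 0, clinic: 15, hospital: 60}
    utilization: {home: 0, clinic: 50, hospital: 75}
    efficacy: {RDS: 25, birth_asphyxia: 25}
  - name: cpap
    role: treatment
    timing: postnatal
    requires_diagnosis: true
    gate: target
    penetration: {home: 0, clinic: 2,  hospital: 20}
    utilization: {home: 0, clinic: 50, hospital: 70}
    efficacy: {RDS: 50, birth_asphyxia: 50}
  - name: surfactant             # intubated/ventilated newborns; hospitals in practice
    role: treatment
    timing: postnatal
    requires_diagnosis: true
    gate: target
    penetration: {home: 0, clinic: 1,  hospital: 5}
    utilization: {home: 0, clinic: 50, hospital: 75}
    efficacy: {RDS: 35}
  - name: sepsis_antibiotics     # empirical antibiotics for suspected neonatal sepsis
    role: treatment
    timing: postnatal
    requires_diagnosis: true
    gate: target
    penetration: {home: 10, clinic: 85, hospital: 95}
    utilization: {home: 20, clinic: 65, hospital: 75}
    efficacy: {sepsis: 72}
transfer:
  destination: hospital
  probabilities: []    # baseline: diagnosed cases are not routinely referred
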