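# Community-acquired pneumonia management plan, declared as a single
# configuration document. Equivalent to the plan built by cap_plan().
plan:
  name: cap_management
  start: triage
  states: [curb65, severity]
  on_discharge: discharged

schemas:
  admission_coding:
    version: "1"
    fields:
      - {name: primary_icd, kind: text, required: true}
      - {name: icd_prefix, kind: text}
  triage:
    version: "1"
    fields:
      - {name: icd_prefix, kind: text, required: true}
  demographics:
    version: "1"
    fields:
      - {name: age, kind: integer, unit: years, required: true}
  vitals:
    version: "1"
    fields:
      - {name: confusion, kind: boolean, required: true}
      - {name: resp_rate, kind: number, unit: breaths/min, required: true}
      - {name: systolic_bp, kind: number, unit: mmHg, required: true}
      - {name: diastolic_bp, kind: number, unit: mmHg, required: true}
  bloods:
    version: "1"
    fields:
      - {name: urea, kind: number, unit: mmol/L, required: true}
  curb65_input:
    version: "1"
    fields:
      - {name: confusion, kind: boolean, required: true}
      - {name: urea, kind: number, unit: mmol/L, required: true, range: [0, 100]}
      - {name: resp_rate, kind: number, unit: breaths/min, required: true, range: [0, 80]}
      - {name: systolic_bp, kind: number, unit: mmHg, required: true, range: [0, 300]}
      - {name: diastolic_bp, kind: number, unit: mmHg, required: true, range: [0, 200]}
      - {name: age, kind: integer, unit: years, required: true, range: [0, 130]}

sources:
  demographics_icd:
    schema: admission_coding
    transforms: [icd_prefix3]
  triage_input:
    schema: triage
    constituents: [demographics_icd]
  demographics_age:
    schema: demographics
  vitals:
    schema: vitals
  bloods:
    schema: bloods
  curb65_input:
    schema: curb65_input
    constituents: [demographics_age, vitals, bloods]

algorithms:
  cap_check:
    type: logical
    schema: triage
    default_label: not_cap
    rules:
      - condition: {field: icd_prefix, op: in,
                    value: [J12, J13, J14, J15, J16, J17, J18]}
        label: cap
  curb65:
    type: curb65

steps:
  triage:
    input: triage_input
    algorithm: cap_check
    decision:
      selector: label
      options: {cap: assess, not_cap: no_cap}
  assess:
    input: curb65_input
    algorithm: curb65
    decision:
      selector: band
      options: {Low: low_severity, Moderate: moderate_severity, High: high_severity}
    actions:
      - {trigger: on_result, state: curb65, from: value}
      - {trigger: on_decision_made, state: severity, from: decision}
  low_severity:
    next_step: assess
  moderate_severity:
    next_step: assess
  high_severity:
    next_step: assess
  no_cap:
    terminal: true
  discharged:
    terminal: true
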