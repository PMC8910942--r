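# Pilot early-access appraisal framework: the draft assessed in the first
# workshop sessions. Eight quantitative and three qualitative criteria;
# therapeutic alternatives was still quantitative at this stage and
# evidence quality had not yet been split into internal/external validity.
version_tag: pilot
core:
  - id: severity
    name: Disease severity at the time of application
    scale:
      minimum: 0
      maximum: 5
      dichotomous: false
      anchor_labels: ["No functional affectation", "Critical situation"]
  - id: urgency
    name: Medical urgency to receive treatment and expected prognostic impact
    scale:
      minimum: 0
      maximum: 5
      dichotomous: false
      anchor_labels: ["Not urgent", "Very urgent"]
  - id: therapeutic_alternatives
    name: Therapeutic alternatives for the patient
    scale:
      minimum: 0
      maximum: 5
      dichotomous: false
      anchor_labels: ["Suitable alternatives available", "No alternatives"]
  - id: efficacy
    name: Efficacy/effectiveness
    scale:
      minimum: 0
      maximum: 5
      dichotomous: false
      anchor_labels: ["Not effective or no data", "Very effective"]
  - id: safety
    name: Safety
    scale:
      minimum: 0
      maximum: 5
      dichotomous: false
      anchor_labels: ["Serious or fatal adverse effects", "Very safe"]
  - id: quality_of_evidence
    name: Quality of evidence
    scale:
      minimum: 0
      maximum: 5
      dichotomous: false
      anchor_labels: ["Low quality", "High quality"]
  - id: therapeutic_benefit
    name: Therapeutic benefit
    scale:
      minimum: 0
      maximum: 5
      dichotomous: false
      anchor_labels: ["No therapeutic benefit", "Cure"]
  - id: plausibility
    name: Plausibility
    scale:
      minimum: 0
      maximum: 5
      dichotomous: false
      anchor_labels: ["Not plausible", "Plausible"]
contextual:
  - id: precedent_coherence
    name: Existence of precedent and coherence of decisions
  - id: management_impact
    name: Management impact
  - id: direct_medical_costs
    name: Direct medical costs
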