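# Final early-access appraisal framework: quantitative core model (weighted,
# scored, aggregated into the value estimate) plus qualitative contextual
# tool (rated favourable / neutral / unfavourable only).
version_tag: final
core:
  - id: severity
    name: Disease severity at the time of application
    scale:
      minimum: 0
      maximum: 5
      dichotomous: false
      anchor_labels:
        - "No functional affectation"
        - "Permanent disability, critical situation or vital support requirement"
    subcriteria:
      - Effect of the disease on patient's morbidity at the time of application
      - Functional impact on patient
    definition: >-
      Functional impact of the disease on the individual patient at the
      moment the request is made.
  - id: urgency
    name: Medical urgency to receive a treatment and expected prognostic impact
    scale:
      minimum: 0
      maximum: 5
      dichotomous: false
      anchor_labels:
        - "Not urgent, slow progression or no sequels"
        - "Very urgent, fulminant progression or severe and permanent sequels"
    subcriteria:
      - Speed of progression
      - Opportunity period for treating the patient
      - Prognostic impact of not receiving the treatment
    definition: >-
      Whether a window of opportunity in prognosis makes early treatment
      necessary to avoid irreversible consequences of the disease.
  - id: efficacy
    name: Efficacy/effectiveness
    scale:
      minimum: 0
      maximum: 5
      dichotomous: false
      anchor_labels:
        - "Not effective or no data"
        - "Very effective"
    subcriteria:
      - End points used
      - Magnitude of health gain
      - Duration of health gain
    definition: >-
      Expected health gain from the treatment; rated non-comparatively
      because early-access requests typically have no comparator.
  - id: safety
    name: Safety
    scale:
      minimum: 0
      maximum: 5
      dichotomous: false
      anchor_labels:
        - "Frequent serious, fatal adverse effects or no data on safety"
        - "Very safe, mild adverse effects"
    subcriteria:
      - Frequent adverse events
      - Serious adverse events
      - Fatal adverse events
      - Discontinuation due to adverse events
    definition: Tolerability and harms profile of the treatment.
  - id: internal_validity
    name: Internal validity
    scale:
      minimum: 0
      maximum: 5
      dichotomous: false
      anchor_labels:
        - "Low internal validity"
        - "High internal validity"
    subcriteria:
      - Quality of evidence
      - Robustness
      - Completeness of reporting
      - Type of evidence
    definition: Methodological quality of the supporting evidence.
  - id: therapeutic_benefit
    name: Therapeutic benefit
    scale:
      minimum: 0
      maximum: 5
      dichotomous: false
      anchor_labels:
        - "No therapeutic benefit"
        - "Cure"
    subcriteria:
      - Type of therapeutic benefit expected of the intervention
    definition: Kind of benefit the intervention can deliver, up to cure.
  - id: external_validity
    name: External validity
    scale:
      minimum: 0
      maximum: 5
      dichotomous: false
      anchor_labels:
        - "Low external validity"
        - "High external validity"
    subcriteria:
      - Representativeness and relevance of the study results for the case requested
    definition: >-
      How well the available study results extrapolate to the individual
      patient of the request.
  - id: plausibility
    name: Plausibility
    scale:
      minimum: 0
      maximum: 5
      dichotomous: true
      anchor_labels:
        - "Not plausible"
        - "Plausible"
    subcriteria:
      - Association between the mechanism of action and the expected effect on the patient
    definition: >-
      All-or-nothing judgement of whether the drug's mechanism of action can
      credibly produce the expected benefit in this patient.
contextual:
  - id: therapeutic_alternatives
    name: Therapeutic alternatives
    subcriteria:
      - Available therapeutic alternatives to treat the patient
    definition: >-
      Whether authorised or suitable alternatives (including clinical
      trials) exist for this patient; lack of alternatives favours approval.
  - id: precedent_coherence
    name: Existence of precedent and coherence of decisions
    subcriteria:
      - Decision on previous applications received for the same drug/indication
      - Number of treatments initiated
    definition: >-
      Consistency and equity with respect to earlier decisions on the same
      drug or indication.
  - id: management_impact
    name: Influence of the decision at a policy level (management impact)
    subcriteria:
      - Possible influence on the negotiation of the price and financing of the drug
    definition: >-
      Potential interference of early use with ongoing pricing and
      reimbursement negotiations.
  - id: costs_budget_impact
    name: Direct medical costs and budget impact
    subcriteria:
      - Treatment cost per patient
      - Other medical costs for treating the patient
      - Potential budget impact
    definition: Economic consequences of granting the request.
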