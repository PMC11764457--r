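# Twelve prognostic variables available at pancreatic-cancer diagnosis,
# with informative marginal priors pooled from a nine-expert quartile
# elicitation. The elicited proportion of each categorical node refers
# to its first-listed category. The published DAG edges are not
# machine-readable, so this network ships edgeless (all nodes are roots
# carrying their elicited marginal prior); users supply conditional
# models to connect nodes. The three continuous priors are
# parameterized as location-scale Student-T of the pooled mean/SD with
# df = complete-case experts minus 1, truncated to the node support
# when sampled; this is an illustrative stand-in, since only the pooled
# moments of those nodes were published.
name: pancreatic_cancer_replica
nodes:
  - id: ca19_9
    kind: continuous
    units: UI/mL
    support: [0.0, .inf]
    prior: {kind: student_t, location: 130.29, scale: 207.84, df: 7}
  - id: age
    kind: continuous
    units: years
    support: [0.0, 110.0]
    prior: {kind: student_t, location: 69.49, scale: 15.69, df: 6}
  - id: tumor_size
    kind: continuous
    units: mm
    support: [0.0, .inf]
    prior: {kind: student_t, location: 23.86, scale: 11.42, df: 7}
  - id: gender
    kind: categorical
    categories: [male, female]
    prior: {kind: beta, alpha: 7.62, beta: 5.76}
  - id: bmi
    kind: categorical
    categories: [normal_overweight, obese]
    prior: {kind: beta, alpha: 10.07, beta: 6.69}
  - id: year_of_diagnosis
    kind: categorical
    categories: [before_2015, from_2015]
    prior: {kind: beta, alpha: 3.85, beta: 2.08}
  - id: tumor_location
    kind: categorical
    categories: [head, body_tail]
    prior: {kind: beta, alpha: 4.26, beta: 3.63}
  - id: diabetes
    kind: categorical
    categories: [absent, present]
    prior: {kind: beta, alpha: 12.52, beta: 10.00}
  - id: symptoms
    kind: categorical
    categories: [absent, present]
    prior: {kind: beta, alpha: 3.46, beta: 2.15}
  - id: asa_score
    kind: categorical
    categories: [I_II, III_IV]
    prior: {kind: beta, alpha: 4.75, beta: 2.94}
  - id: resectability
    kind: categorical
    categories: [resectable, borderline_locally_advanced]
    prior: {kind: beta, alpha: 3.83, beta: 2.13}
  - id: neoadjuvant
    kind: categorical
    categories: [performed, not_performed]
    prior: {kind: beta, alpha: 3.46, beta: 2.22}
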