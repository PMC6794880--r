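# Criteria hierarchy for interventional cancer-pain treatment selection.
# Same structure as the built-in pain_case_study() hierarchy; shipped as an
# example of the configuration format accepted by build_hierarchy().
main:
- id: C1
  label: Convenience
- id: C2
  label: Pain
- id: C3
  label: Risk
- id: C4
  label: Duration
- id: C5
  label: Cost
leaves:
- id: C11
  parent: C1
  label: General medical condition
  scale: {Poor: 3, Med: 2, Well: 1}
- id: C12
  parent: C1
  label: Stage of cancer
  scale: {Early: 1, Med: 2, Late: 3}
- id: C13
  parent: C1
  label: Level of evidence
  scale: {Low: 1, Med: 2, High: 3}
- id: C21
  parent: C2
  label: Localization of pain
  scale: {Local: 1, Med: 2, Extensive: 3}
- id: C22
  parent: C2
  label: Character of pain
  scale: {Visceral: 1, VisceralPlus: 2, Mixed: 3}
- id: C31
  parent: C3
  label: Risk of complication
  scale: {High: 1, Med: 2, Low: 3}
- id: C32
  parent: C3
  label: Radiation exposure
  scale: {High: 1, Med: 2, Low: 3}
- id: C41
  parent: C4
  label: Duration of procedure
  scale: {Long: 1, Med: 2, Short: 3}
- id: C42
  parent: C4
  label: Persistency
  scale: {Short: 1, Med: 2, Long: 3}
- id: C51
  parent: C5
  label: Material cost
  scale: {High: 1, Med: 2, Low: 3}
- id: C52
  parent: C5
  label: Cost of hospitalization
  scale: {Long: 1, Med: 2, Short: 3}
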