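boxes:
- kind: response
  variables:
  - name: csa_dis
    log: yes
    units: mm^2
  - name: vbmd_tot_dis
    log: yes
    units: mg/cm^3
  - name: vbmd_trab_dis
    log: yes
    units: mg/cm^3
  - name: csa_dia
    log: yes
    units: mm^2
  - name: cort_area_dia
    log: yes
    units: mm^2
  - name: cort_vbmd_dia
    log: yes
    units: mg/cm^3
  - name: ssi_dia
    log: yes
    units: mm^3
- kind: response
  variables:
  - name: lean_mass
    log: yes
    units: kg
  - name: fat_mass_pct
    log: yes
    units: '%'
  - name: height
    log: yes
    units: m
- kind: response
  variables:
  - name: adiponectin
    log: yes
    units: ug/L
  - name: leptin
    log: yes
    units: ug/L
  - name: osteocalcin
    log: yes
    units: ug/L
  - name: ucoc
    log: yes
    units: ug/L
  - name: phylloquinone
    log: yes
    units: ug/L
- kind: context
  variables:
  - name: age
    log: yes
    units: 'y'
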