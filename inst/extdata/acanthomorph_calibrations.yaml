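schema: divtime-calibrations/1
calibrations:
- name: A
  taxa:
  - clade:Polymixiidae
  kind: lognormal_offset
  fossil: yes
  offset: 93.5
  meanlog: 2.611174035521092
  sdlog: 0.75
- name: B
  taxa:
  - clade:Zeidae
  kind: lognormal_offset
  fossil: yes
  offset: 55.799999999999997
  meanlog: 2.094986468613716
  sdlog: 0.75
- name: C
  taxa:
  - clade:Percomorpha
  kind: uniform
  fossil: yes
  min: 96.900000000000006
  max: 150.900000000000006
- name: D
  taxa:
  - clade:Gempylidae+Scombridae
  kind: lognormal_offset
  fossil: yes
  offset: 61.700000000000003
  meanlog: 2.195496530137793
  sdlog: 0.75
- name: E
  taxa:
  - clade:Cichlidae_Africa+Neotropics
  kind: normal
  fossil: no
  mean: 110.0
  sd: 6.020518791710918
- name: F
  taxa:
  - clade:Labrini
  kind: uniform
  fossil: no
  min: 14.0
  max: 20.5
- name: G
  taxa:
  - clade:Gasterosteiformes+Tetraodontiformes
  kind: uniform
  fossil: yes
  min: 96.900000000000006
  max: 150.900000000000006
- name: H
  taxa:
  - clade:Chaunacidae
  kind: lognormal_offset
  fossil: yes
  offset: 37.200000000000003
  meanlog: 1.689521360505552
  sdlog: 0.75
- name: I
  taxa:
  - clade:Monacanthidae
  kind: lognormal_offset
  fossil: yes
  offset: 48.600000000000001
  meanlog: 1.956836130132899
  sdlog: 0.75
- name: J
  taxa:
  - clade:Takifugu+Tetraodon
  kind: uniform
  fossil: yes
  min: 32.25
  max: 56.0
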