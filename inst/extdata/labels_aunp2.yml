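rules:
- resname: LIG
  name: S
  role: SULFUR
- resname: LIG
  name: C1
  role: ALKYL_C1
- resname: LIG
  name: C2
  role: ALKYL_C2
- resname: LIG
  name: C3
  role: ALKYL_C3
- resname: LIG
  name: C4
  role: ALKYL_C4
- resname: LIG
  name: C5
  role: ALKYL_C5
- resname: LIG
  name: C6
  role: ALKYL_C6
- resname: LIG
  name: C7
  role: ALKYL_C7
- resname: LIG
  name: O8
  role: O8
- resname: LIG
  name: N9
  role: N9
- resname: LIG
  name: C12
  role: LINKER_12
- resname: LIG
  name: C15
  role: LINKER_15
- resname: LIG
  name: N18
  role: N18
- resname: LIG
  name: O19
  role: O19
- resname: LIG
  name: NT1
  role: TACN_N
- resname: LIG
  name: NT2
  role: TACN_N
- resname: LIG
  name: NT3
  role: TACN_N
- resname: LIG
  name: ZN
  role: ZN
- resname: LIG
  name: H1
  role: OTHER
- resname: LIG
  name: H2
  role: OTHER
- resname: LIG
  name: H3
  role: OTHER
- resname: LIG
  name: H4
  role: OTHER
- resname: LIG
  name: H5
  role: OTHER
- resname: LIG
  name: H6
  role: OTHER
- resname: LIG
  name: H7
  role: OTHER
- resname: LIG
  name: HN9
  role: OTHER
- resname: LIG
  name: HN18
  role: OTHER
- resname: LIG
  name: H12
  role: OTHER
- resname: LIG
  name: H15
  role: OTHER
- resname: AUC
  name: AU
  role: GOLD
- resname: HPN
  name: P
  role: SUB_P
- resname: HPN
  name: O3
  role: SUB_O3
- resname: HPN
  name: O4
  role: SUB_O4
- resname: HPN
  name: O5
  role: SUB_O5
- resname: SOL
  name: OW
  role: WATER_O
- resname: SOL
  name: HW1
  role: WATER_H
- resname: SOL
  name: HW2
  role: WATER_H
- resname: CL
  name: CL
  role: CL
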