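{
  "CD3+/HLA-DR+": "Activated T cells expressing the late activation marker HLA-DR",
  "CD3+/HLA-DR+/CD69+/CD134-": "Activated T cells with early (CD69) and late (HLA-DR) activation markers, lacking CD134",
  "CD3+/HLA-DR+/CD134+/CD69-": "Late-activated T cells expressing CD134 without CD69",
  "CD3+/CD134+": "T cells expressing the late activation marker CD134 (OX40)",
  "CD3+/CD86+": "Activated / effector-memory T cells expressing CD86",
  "CD4+/CD45RA+": "Naive T helper cells",
  "CD4+/CD45RO+": "Memory T helper cells",
  "CD4+/CD27+": "Naive and memory T helper cells",
  "Total CD8+": "Total cytotoxic T cells",
  "CD8+/CD45RA-": "Memory cytotoxic T cells",
  "CD8+/CD45RO+": "Memory cytotoxic T cells",
  "CD8+/CD27-": "Effector cytotoxic T cells",
  "CD19+/CD80+": "Activated B cells",
  "CD19+/CD86+": "Activated B cells expressing CD86",
  "CD3-/CD56+/CD16+": "Cytotoxic NK cells",
  "CD3-/CD56+/CD16+/CD134+": "Cytotoxic NK cells expressing a marker of stimulation",
  "CD3-/CD56+/CD16+/CD107a/b+": "Cytotoxic NK cells expressing a marker of degranulation",
  "CD3-/CD56+/CD16+/CD159a+": "Cytotoxic NK cells expressing the inhibitory receptor NKG2A"
}
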