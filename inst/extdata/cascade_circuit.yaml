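format: partpool-circuit
version: 1
compartments:
  nucleus: 3.0e-15
  cytoplasm: 3.0e-14
chemical_inputs: []
pools:
- name: RNAP
  carrier: RNA_polymerase
  compartment: nucleus
  initial_copies: 300.0
  conserved: yes
  chem_bind_rate: 0.001
  chem_unbind_rate: 0.001
- name: ribosome
  carrier: ribosome
  compartment: cytoplasm
  initial_copies: 2000.0
  conserved: yes
  chem_bind_rate: 0.001
  chem_unbind_rate: 0.001
- name: spliceosome
  carrier: machinery
  compartment: nucleus
  initial_copies: 200.0
  conserved: yes
  chem_bind_rate: 0.001
  chem_unbind_rate: 0.001
- name: Dicer
  carrier: machinery
  compartment: nucleus
  initial_copies: 200.0
  conserved: yes
  chem_bind_rate: 0.001
  chem_unbind_rate: 0.001
- name: RISC
  carrier: machinery
  compartment: cytoplasm
  initial_copies: 2000.0
  conserved: yes
  chem_bind_rate: 0.001
  chem_unbind_rate: 0.001
- name: act1
  carrier: transcription_factor
  compartment: nucleus
  initial_copies: 500.0
  conserved: no
  degradation_rate: 0.0001
  production_rate: 0.05
  chem_bind_rate: 0.005
  chem_unbind_rate: 0.001
units:
- name: u_gfp
  promoter:
    name: p_gfp
    tf_bindings:
    - tf_name: act1
      role: activator
      n_operators: 1
      cooperative: no
      base_bind_rate: 0.001
      unbind_rate: 0.1
      affinity_gradient: 1.0
      cooperativity_factor: 1.0
    rnap_bind_rate: 0.001
    rnap_unbind_rate: 0.1
    clearing_rate: 0.05
    leak_rate: 1.0e-08
  cargo:
    type: coding_region
    name: gfp_cds
    product_name: gfp
    product_kind: reporter
    riboswitches: []
    sirna_targets:
    - sirna_name: si_r
      n_sites: 2
      bind_rate: 0.001
      cleavage_rate: 0.005
    splice_bind_rate: 0.001
    splice_unbind_rate: 0.1
    splice_cat_rate: 0.05
    export_rate: 0.01
    ribosome_bind_rate: 0.0001
    ribosome_unbind_rate: 0.01
    translation_rate: 0.1
  terminator:
    name: t_gfp
    transcript_decay_rate: 0.0002
- name: u_sir
  promoter:
    name: p_sir
    tf_bindings: []
    rnap_bind_rate: 0.001
    rnap_unbind_rate: 0.1
    clearing_rate: 0.05
    leak_rate: 1.0e-08
  cargo:
    type: sirna_gene
    sirna_name: si_r
    dicer_bind_rate: 0.001
    dicer_unbind_rate: 0.1
    dicer_cat_rate: 0.05
    export_rate: 0.01
    risc_load_rate: 0.001
    risc_unload_rate: 0.0002
  terminator:
    name: t_sir
    transcript_decay_rate: 0.0002
parameters: []
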