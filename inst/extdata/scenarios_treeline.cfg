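[IT-For]
site: Lav
forcing_side: below
counterfactual: no
h_e: 20
group: deciduous_tree_suppressed 1 2.5 0.3 no 0.1 10 0.5
group: evergreen_needleleaf_tree 4 20 2 yes 0.1 12 0.5

[IT-Un]
site: Lav
forcing_side: below
counterfactual: yes
h_e: 20
group: deciduous_tree_suppressed 1 2.5 0.3 no 0.1 10 0.5

[IT-Alp]
site: MBo
forcing_side: above
counterfactual: no
h_e: 20
group: grass_or_sedge 1.5 0.3 0 no 0.1 15 0.5

[IT-Tr]
site: MBo
forcing_side: above
counterfactual: yes
h_e: 20
group: deciduous_tree_suppressed 1 2.5 0.3 no 0.1 10 0.5
group: evergreen_needleleaf_tree 4 20 2 yes 0.1 12 0.5

[US-For]
site: NR1
forcing_side: below
counterfactual: no
h_e: 12
group: shrub 1 0.8 0.05 no 0.1 10 0.5
group: evergreen_needleleaf_tree 4 12 2 yes 0.1 12 0.5

[US-Un]
site: NR1
forcing_side: below
counterfactual: yes
h_e: 12
group: shrub 1 0.8 0.05 no 0.1 10 0.5

[US-Alp]
site: T-Van
forcing_side: above
counterfactual: no
h_e: 12
group: grass_or_sedge 1.5 0.25 0 no 0.1 15 0.5

[US-Tr]
site: T-Van
forcing_side: above
counterfactual: yes
h_e: 12
group: shrub 1 0.8 0.05 no 0.1 10 0.5
group: evergreen_needleleaf_tree 4 12 2 yes 0.1 12 0.5

[CA-For]
site: HPC
forcing_side: below
counterfactual: no
h_e: 8
group: shrub 1 0.6 0.05 no 0.1 10 0.5
group: evergreen_needleleaf_tree 0.5 8 1 yes 0.1 12 0.5

[CA-Un]
site: HPC
forcing_side: below
counterfactual: yes
h_e: 8
group: shrub 1 0.6 0.05 no 0.1 10 0.5

[CA-Arc]
site: TVC
forcing_side: above
counterfactual: no
h_e: 8
group: shrub 1 0.5 0.05 no 0.1 10 0.5

[CA-Tr]
site: TVC
forcing_side: above
counterfactual: yes
h_e: 8
group: shrub 1 0.6 0.05 no 0.1 10 0.5
group: evergreen_needleleaf_tree 0.5 8 1 yes 0.1 12 0.5

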