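data_toy
#
loop_
_atom_site.group_PDB
_atom_site.id
_atom_site.type_symbol
_atom_site.label_atom_id
_atom_site.label_comp_id
_atom_site.label_asym_id
_atom_site.auth_asym_id
_atom_site.label_seq_id
_atom_site.auth_seq_id
_atom_site.Cartn_x
_atom_site.Cartn_y
_atom_site.Cartn_z
_atom_site.occupancy
_atom_site.B_iso_or_equiv
_atom_site.pdbx_PDB_model_num
ATOM 1 N N ALA A A 1 1 0 0 0 1 0 1
ATOM 2 C CA ALA A A 1 1 1.458 0 0 1 0 1
ATOM 3 C C ALA A A 1 1 2.0095 1.4218 0 1 0 1
ATOM 4 N N ALA A A 2 2 1.4634 2.2629 0.8721 1 0 1
ATOM 5 C CA ALA A A 2 2 1.8994 3.6505 0.9743 1 0 1
ATOM 6 C C ALA A A 2 2 1.7682 4.3698 -0.364 1 0 1
ATOM 7 N N ALA A A 3 3 0.6176 4.205 -1.0084 1 0 1
ATOM 8 C CA ALA A A 3 3 0.3638 4.8378 -2.2971 1 0 1
ATOM 9 C C ALA A A 3 3 1.4211 4.4433 -3.3229 1 0 1
ATOM 10 N N ALA A A 4 4 1.7114 3.1485 -3.3981 1 0 1
ATOM 11 C CA ALA A A 4 4 2.7039 2.6392 -4.3368 1 0 1
ATOM 12 C C ALA A A 4 4 4.0574 3.3093 -4.1259 1 0 1
ATOM 13 N N ALA A A 5 5 4.4839 3.3878 -2.8696 1 0 1
ATOM 14 C CA ALA A A 5 5 5.7609 4.0045 -2.5312 1 0 1
ATOM 15 C C ALA A A 5 5 5.8297 5.4423 -3.0349 1 0 1
ATOM 16 N N ALA A A 6 6 4.771 6.2044 -2.7807 1 0 1
ATOM 17 C CA ALA A A 6 6 4.7092 7.5971 -3.2075 1 0 1
ATOM 18 C C ALA A A 6 6 4.8994 7.7207 -4.7156 1 0 1
ATOM 19 N N ALA A A 7 7 4.1874 6.8872 -5.467 1 0 1
ATOM 20 C CA ALA A A 7 7 4.2763 6.9016 -6.9222 1 0 1
ATOM 21 C C ALA A A 7 7 5.7118 6.6848 -7.3891 1 0 1
ATOM 22 N N ALA A A 8 8 6.3723 5.6866 -6.8115 1 0 1
ATOM 23 C CA ALA A A 8 8 7.751 5.373 -7.1672 1 0 1
ATOM 24 C C ALA A A 8 8 8.6602 6.5811 -6.9682 1 0 1
ATOM 25 N N ALA A A 9 9 8.5278 7.2319 -5.8171 1 0 1
ATOM 26 C CA ALA A A 9 9 9.3365 8.4034 -5.5018 1 0 1
ATOM 27 C C ALA A A 9 9 9.1715 9.4886 -6.5604 1 0 1
ATOM 28 N N ALA A A 10 10 7.9243 9.768 -6.9248 1 0 1
ATOM 29 C CA ALA A A 10 10 7.6286 10.7846 -7.9272 1 0 1
ATOM 30 C C ALA A A 10 10 8.3391 10.4849 -9.2429 1 0 1
ATOM 31 N N ALA A A 11 11 8.2473 9.236 -9.6881 1 0 1
ATOM 32 C CA ALA A A 11 11 8.8806 8.818 -10.933 1 0 1
ATOM 33 C C ALA A A 11 11 10.3807 9.0913 -10.9075 1 0 1
ATOM 34 N N ALA A A 12 12 11.0279 8.7107 -9.8109 1 0 1
ATOM 35 C CA ALA A A 12 12 12.4637 8.914 -9.6593 1 0 1
ATOM 36 C C ALA A A 12 12 12.8316 10.386 -9.8128 1 0 1
ATOM 37 N N ALA A A 13 13 12.0832 11.2514 -9.1367 1 0 1
ATOM 38 C CA ALA A A 13 13 12.329 12.6873 -9.1966 1 0 1
ATOM 39 C C ALA A A 13 13 12.2754 13.1965 -10.6331 1 0 1
ATOM 40 N N ALA A A 14 14 11.2417 12.7886 -11.362 1 0 1
ATOM 41 C CA ALA A A 14 14 11.072 13.2024 -12.7497 1 0 1
ATOM 42 C C ALA A A 14 14 12.2876 12.826 -13.5901 1 0 1
ATOM 43 N N ALA A A 15 15 12.7423 11.586 -13.4418 1 0 1
ATOM 44 C CA ALA A A 15 15 13.8976 11.0995 -14.1862 1 0 1
ATOM 45 C C ALA A A 15 15 15.1221 11.9738 -13.9374 1 0 1
ATOM 46 N N ALA A A 16 16 15.3782 12.2777 -12.6692 1 0 1
ATOM 47 C CA ALA A A 16 16 16.5182 13.1059 -12.295 1 0 1
ATOM 48 C C ALA A A 16 16 16.4706 14.4592 -12.9965 1 0 1
#
_struct_conf.conf_type_id        HELX_P
_struct_conf.id                  1
_struct_conf.beg_label_asym_id   A
_struct_conf.beg_auth_seq_id     3
_struct_conf.end_label_asym_id   A
_struct_conf.end_auth_seq_id     14
#
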