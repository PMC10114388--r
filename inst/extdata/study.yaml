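n_blocks:
- 0
- 35
- 70
- 105
- 140
- 175
- 210
- 245
- 280
- 315
cases:
- tensile
- shear
- rotation
voxel_um: 4.0
sheet_voxel_um:
- 4.0
- 3.875
- 4.0
include_sheet: yes
tensile_Pa: 0.15
shear_Pa: 0.0009
rotation_deg: 30.0
rows: 3
cols: 5
fibre_dims_um:
- 300.0
- 20.0
- 20.0
elastin_dims_um:
- 20.0
- 12.0
- 12.0
gap_um: 20.0
bone_thickness_um: 40.0
sheet_dims_um:
- 300.0
- 62.0
- 128.0
materials:
  collagen:
    E_Pa: 8900000.0
    nu: 0.48
  elastin:
    E_Pa: 4000000.0
    nu: 0.48
  sheet:
    E_Pa: 1.27e+07
    nu: 0.48
  bone:
    E_Pa: 1.7e+07
    nu: 0.3
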