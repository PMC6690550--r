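class_label: ring_a
arrangement: ring
pore_mixture: 280:30:0.1;26:4:0.9
ring_period: 700
earlywood_fraction: 0.25
pores_per_mm2: 60
wall_gray: 118
lumen_gray: 232
ray_lines_per_mm: 0.8
ray_width: 12
noise_sd: 10
seed: 1
earlywood_min_diameter: 100

class_label: ring_b
arrangement: ring
pore_mixture: 340:40:0.08;35:6:0.92
ring_period: 900
earlywood_fraction: 0.3
pores_per_mm2: 45
wall_gray: 128
lumen_gray: 238
ray_lines_per_mm: 0.5
ray_width: 15
noise_sd: 10
seed: 1
earlywood_min_diameter: 100

class_label: ring_c
arrangement: ring
pore_mixture: 200:25:0.12;12:2:0.88
ring_period: 500
earlywood_fraction: 0.3
pores_per_mm2: 90
wall_gray: 112
lumen_gray: 226
ray_lines_per_mm: 1.2
ray_width: 10
noise_sd: 10
seed: 1
earlywood_min_diameter: 100

class_label: ring_d
arrangement: ring
pore_mixture: 250:30:0.1;45:8:0.9
ring_period: 800
earlywood_fraction: 0.22
pores_per_mm2: 50
wall_gray: 132
lumen_gray: 242
ray_lines_per_mm: 0.6
ray_width: 18
noise_sd: 10
seed: 1
earlywood_min_diameter: 100

class_label: ring_e
arrangement: ring
pore_mixture: 310:35:0.07;28:5:0.93
ring_period: 600
earlywood_fraction: 0.35
pores_per_mm2: 70
wall_gray: 122
lumen_gray: 230
ray_lines_per_mm: 1
ray_width: 12
noise_sd: 10
seed: 1
earlywood_min_diameter: 100

class_label: cerris_like
arrangement: ring
pore_mixture: 320:35:0.05;18:3:0.95
ring_period: 750
earlywood_fraction: 0.28
pores_per_mm2: 100
wall_gray: 120
lumen_gray: 231
ray_lines_per_mm: 0.9
ray_width: 12
noise_sd: 10
seed: 1
earlywood_min_diameter: 100

class_label: diffuse_a
arrangement: diffuse
pore_mixture: 60:10:1
pores_per_mm2: 40
wall_gray: 115
lumen_gray: 228
ray_lines_per_mm: 0.7
ray_width: 12
noise_sd: 10
seed: 1
earlywood_min_diameter: 100

class_label: diffuse_b
arrangement: diffuse
pore_mixture: 85:14:1
pores_per_mm2: 25
wall_gray: 125
lumen_gray: 236
ray_lines_per_mm: 0.4
ray_width: 16
noise_sd: 10
seed: 1
earlywood_min_diameter: 100

class_label: diffuse_c
arrangement: diffuse
pore_mixture: 40:7:1
pores_per_mm2: 80
wall_gray: 110
lumen_gray: 224
ray_lines_per_mm: 1.1
ray_width: 10
noise_sd: 10
seed: 1
earlywood_min_diameter: 100

class_label: diffuse_d
arrangement: diffuse
pore_mixture: 110:18:1
pores_per_mm2: 16
wall_gray: 130
lumen_gray: 240
ray_lines_per_mm: 0.5
ray_width: 14
noise_sd: 10
seed: 1
earlywood_min_diameter: 100

class_label: diffuse_e
arrangement: diffuse
pore_mixture: 70:12:0.6;30:6:0.4
pores_per_mm2: 55
wall_gray: 120
lumen_gray: 233
ray_lines_per_mm: 0.8
ray_width: 12
noise_sd: 10
seed: 1
earlywood_min_diameter: 100

class_label: diffuse_f
arrangement: diffuse
pore_mixture: 95:15:0.5;50:8:0.5
pores_per_mm2: 30
wall_gray: 135
lumen_gray: 244
ray_lines_per_mm: 0.3
ray_width: 20
noise_sd: 10
seed: 1
earlywood_min_diameter: 100

class_label: radial_a
arrangement: radial
pore_mixture: 30:5:1
pores_per_mm2: 100
wall_gray: 114
lumen_gray: 227
ray_lines_per_mm: 1.3
ray_width: 10
noise_sd: 10
seed: 1
earlywood_min_diameter: 100

class_label: radial_b
arrangement: radial
pore_mixture: 48:8:1
pores_per_mm2: 70
wall_gray: 124
lumen_gray: 235
ray_lines_per_mm: 0.9
ray_width: 13
noise_sd: 10
seed: 1
earlywood_min_diameter: 100

class_label: radial_c
arrangement: radial
pore_mixture: 24:4:0.7;55:9:0.3
pores_per_mm2: 110
wall_gray: 118
lumen_gray: 229
ray_lines_per_mm: 1.5
ray_width: 9
noise_sd: 10
seed: 1
earlywood_min_diameter: 100

class_label: radial_d
arrangement: radial
pore_mixture: 65:10:1
pores_per_mm2: 45
wall_gray: 129
lumen_gray: 239
ray_lines_per_mm: 0.6
ray_width: 15
noise_sd: 10
seed: 1
earlywood_min_diameter: 100

class_label: radial_e
arrangement: radial
pore_mixture: 38:6:0.5;14:3:0.5
pores_per_mm2: 130
wall_gray: 116
lumen_gray: 225
ray_lines_per_mm: 1.2
ray_width: 11
noise_sd: 10
seed: 1
earlywood_min_diameter: 100

class_label: ilex_like
arrangement: radial
pore_mixture: 18:3:1
pores_per_mm2: 120
wall_gray: 120
lumen_gray: 231
ray_lines_per_mm: 0.9
ray_width: 12
noise_sd: 10
seed: 1
earlywood_min_diameter: 100
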