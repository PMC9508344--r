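segments:
- name: pelvis
  parent: ''
  jx: 0.0
  jy: 0.0
  mass: 8.2
  inertia: 0.035
  cx: 0.0
  cy: 0.0
- name: trunk
  parent: pelvis
  jx: 0.0
  jy: 0.1
  mass: 27.0
  inertia: 1.1
  cx: 0.0
  cy: 0.26
- name: arms
  parent: trunk
  jx: 0.0
  jy: 0.42
  mass: 7.0
  inertia: 1.2
  cx: 0.0
  cy: -0.35
- name: thigh_r
  parent: pelvis
  jx: 0.0
  jy: -0.06
  mass: 10.1
  inertia: 0.16
  cx: 0.0
  cy: -0.2
- name: shank_r
  parent: thigh_r
  jx: 0.0
  jy: -0.47
  mass: 3.9
  inertia: 0.055
  cx: 0.0
  cy: -0.2
- name: foot_r
  parent: shank_r
  jx: 0.0
  jy: -0.46
  mass: 1.0
  inertia: 0.005
  cx: 0.06
  cy: -0.05
- name: thigh_l
  parent: pelvis
  jx: 0.0
  jy: -0.06
  mass: 10.1
  inertia: 0.16
  cx: 0.0
  cy: -0.2
- name: shank_l
  parent: thigh_l
  jx: 0.0
  jy: -0.47
  mass: 3.9
  inertia: 0.055
  cx: 0.0
  cy: -0.2
- name: foot_l
  parent: shank_l
  jx: 0.0
  jy: -0.46
  mass: 1.0
  inertia: 0.005
  cx: 0.06
  cy: -0.05
spheres:
- name: heel_r
  segment: foot_r
  x: -0.04
  'y': -0.07
  radius: 0.03
  stiffness: 3000000.0
  dissipation: 2.0
  friction: 0.8
  v_smooth: 0.15
  delta_smooth: 0.0001
  foot: right
- name: toe_med_r
  segment: foot_r
  x: 0.175
  'y': -0.07
  radius: 0.03
  stiffness: 1500000.0
  dissipation: 2.0
  friction: 0.8
  v_smooth: 0.15
  delta_smooth: 0.0001
  foot: right
- name: toe_lat_r
  segment: foot_r
  x: 0.175
  'y': -0.07
  radius: 0.03
  stiffness: 1500000.0
  dissipation: 2.0
  friction: 0.8
  v_smooth: 0.15
  delta_smooth: 0.0001
  foot: right
- name: heel_l
  segment: foot_l
  x: -0.04
  'y': -0.07
  radius: 0.03
  stiffness: 3000000.0
  dissipation: 2.0
  friction: 0.8
  v_smooth: 0.15
  delta_smooth: 0.0001
  foot: left
- name: toe_med_l
  segment: foot_l
  x: 0.175
  'y': -0.07
  radius: 0.03
  stiffness: 1500000.0
  dissipation: 2.0
  friction: 0.8
  v_smooth: 0.15
  delta_smooth: 0.0001
  foot: left
- name: toe_lat_l
  segment: foot_l
  x: 0.175
  'y': -0.07
  radius: 0.03
  stiffness: 1500000.0
  dissipation: 2.0
  friction: 0.8
  v_smooth: 0.15
  delta_smooth: 0.0001
  foot: left
drag:
  rho: 1.225
  cd: 0.9
  area: 0.45
gravity: 9.81
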