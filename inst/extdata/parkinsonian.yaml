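populations:
  e:
    Qmax: 300.0
    theta: 14.0
    excitatory: yes
  r:
    Qmax: 300.0
    theta: 13.0
    excitatory: no
  s:
    Qmax: 300.0
    theta: 13.0
    excitatory: yes
  d1:
    Qmax: 65.0
    theta: 19.0
    excitatory: no
  d2:
    Qmax: 65.0
    theta: 19.0
    excitatory: no
  p1:
    Qmax: 250.0
    theta: 10.0
    excitatory: no
  p2:
    Qmax: 300.0
    theta: 9.0
    excitatory: no
  z:
    Qmax: 500.0
    theta: 10.0
    excitatory: yes
connections:
  ee:
    nu: 1.2
  ei:
    nu: -1.5
  es:
    nu: 1.1
    tau: 0.035
  re:
    nu: 0.1
    tau: 0.045
  rs:
    nu: 0.1
  se:
    nu: 1.5
    tau: 0.045
  sr:
    nu: -0.1
  sp1:
    nu: -0.2
  sn:
    nu: 0.5
  d1e:
    nu: 0.1
  d1s:
    nu: 1.0
  d1d1:
    nu: -0.02
  d2e:
    nu: 0.1
  d2s:
    nu: 0.1
  d2d2:
    nu: -0.02
  p1d1:
    nu: -0.2
  p1p2:
    nu: -0.02
  p1z:
    nu: 1.0
  p2d2:
    nu: -0.8
  p2p2:
    nu: -0.2
  p2z:
    nu: 2.4
  ze:
    nu: 1.3
  zp2:
    nu: -0.2
sigma: 3.3
alpha: 50.0
beta: 200.0
gamma_e: 116.0
r_e: 80.0
phi_n: 1.0
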