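variant: all_types
seed: 1
noise_sigma: 0.17
populations:
  A:
    size: 200.0
    bias: 8.35
    excitatory: yes
  B:
    size: 200.0
    bias: 8.35
    excitatory: yes
  C:
    size: 200.0
    bias: 8.35
    excitatory: yes
  D:
    size: 200.0
    bias: 8.35
    excitatory: yes
  IN:
    size: 200.0
    bias: 4.0
    excitatory: no
connections:
- pre: A
  post: B
  kind: depression
  weight: 3.2
- pre: B
  post: A
  kind: depression
  weight: 3.2
- pre: C
  post: D
  kind: depression
  weight: 3.2
- pre: D
  post: C
  kind: depression
  weight: 3.2
- pre: A
  post: D
  kind: facilitation
  weight: 1.55
- pre: D
  post: A
  kind: facilitation
  weight: 1.55
- pre: B
  post: C
  kind: facilitation
  weight: 1.55
- pre: C
  post: B
  kind: facilitation
  weight: 1.55
- pre: A
  post: A
  kind: constant
  weight: 1.7
- pre: B
  post: B
  kind: constant
  weight: 1.7
- pre: C
  post: C
  kind: constant
  weight: 1.7
- pre: D
  post: D
  kind: constant
  weight: 1.7
- pre: A
  post: IN
  kind: constant
  weight: 0.7
- pre: B
  post: IN
  kind: constant
  weight: 0.7
- pre: C
  post: IN
  kind: constant
  weight: 0.7
- pre: D
  post: IN
  kind: constant
  weight: 0.7
- pre: IN
  post: A
  kind: inhibitory
  weight: 5.0
- pre: IN
  post: B
  kind: inhibitory
  weight: 5.0
- pre: IN
  post: C
  kind: inhibitory
  weight: 5.0
- pre: IN
  post: D
  kind: inhibitory
  weight: 5.0
plasticity:
  U: 0.2
  facilitation:
    tau_u: 600.0
    tau_x: 100.0
  depression:
    tau_u: 20.0
    tau_x: 600.0
  tau_s_exc: 100.0
  tau_s_inh: 20.0
protocol:
  activation_amplitude: 0.35
  activation_ramp: 200.0
  sensory_amplitude: 0.2
  sensory_width: 200.0
  sensory_target: G1
  perturbation_amplitude: 0.0
  perturbation_onset: 0.0
  perturbation_width: 200.0
  perturbation_target: A1
  goal_display_onset: 500.0
  trial_duration: 4000.0
  go_time: 3000.0
meanfield:
  goal_weight: 1.9
  perturbation_amplitude: 0.01
  perturbation_width: 200.0
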