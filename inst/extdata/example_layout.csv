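label,alpha_deg,z_cm,r_cm,required_force_N
cupboard-front-shelf,0,139,40,35
cupboard-deep-shelf,0,139,66,35
pot-on-counter,30,109,35,60
kettle-far-corner,60,139,75,20
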