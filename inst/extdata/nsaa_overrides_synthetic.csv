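token_pattern,delta_mass_Da,kd_value,charge,polar_flag
eK-eK-yE-C20DA,725.97,3.8,0,0
yE-C16,367.53,3.5,0,0
yE-C18,395.58,3.6,0,0
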