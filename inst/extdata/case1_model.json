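{"descriptors":["D1","D2","D3","D4"],"initial":[0.5,0.25,0.25,0],"phases":[{"first_step":0,"matrix":{"D1":[0.5,0.3,0.2,0],"D2":[0.1,0.5,0.3,0.1],"D3":[0.1,0.2,0.5,0.2],"D4":[0,0,0.4,0.6]}},{"first_step":7,"matrix":{"D1":[0.4,0.3,0.2,0.1],"D2":[0.1,0.4,0.3,0.2],"D3":[0.1,0.1,0.6,0.2],"D4":[0.1,0.1,0.2,0.6]}},{"first_step":14,"matrix":{"D1":[0.2,0.2,0.3,0.3],"D2":[0.1,0.3,0.3,0.3],"D3":[0.1,0.2,0.3,0.4],"D4":[0.1,0,0.2,0.7]}}],"n_steps":20}
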