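# basis: mass fraction of fructose in fructose + glycerol
T_K,x_mass,sigma
308.15,0.2270,0.0036
318.15,0.2942,0.0030
328.15,0.3440,0.0038
338.15,0.4089,0.0043
351.15,0.4734,0.0099
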