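{"metabolites":[{"id":"A"},{"id":"B"}],"reactions":[{"id":"EX_A","stoichiometry":{"A":1},"lower_bound":0,"upper_bound":10,"subsystem":"Transport"},{"id":"R_AB","stoichiometry":{"A":-1,"B":1},"lower_bound":0,"upper_bound":10,"subsystem":"Core pathway","gpr":"g1"},{"id":"EX_B","stoichiometry":{"B":-1},"lower_bound":0,"upper_bound":10,"subsystem":"Transport"}]}
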