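[arrived/VBD nsubj>I/PRP nmod>[appointment/NN case>to/IN nmod:poss>my/PRP$] nmod>[time/NN case>on/IN] cc>and/CC conj>[waited/VBD nmod>[room/NN case>in/IN nmod:poss>his/PRP$ compound>waiting/NN] nmod>[hour/NN case>for/IN det>an/DT advmod>over/RB]]]
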