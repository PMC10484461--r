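# Irregular plural map applied before stemming: surface <TAB> replacement.
children	child
feet	foot
teeth	tooth
mice	mouse
men	man
women	woman
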