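>A
(a w -d -c y b -z -e f x i j h g)
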