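no
not
without
denies
denied
negative for
no evidence of
no signs of
free of
rules out
ruled out
absence of
never
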