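group,nonresponder,responder
excluded_ignored,35,4
inflamed,4,6
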