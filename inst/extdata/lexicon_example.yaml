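# Example custom lexicon: three categories, one list of literal terms each.
# The builtin Chinese lexicon is available as load_lexicon("hpu-china-2003").
name: toy-english
health: [health, hospital]
policy: [policy, government, regulation]
uncertainty: [uncertain, unpredictable, volatile]
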