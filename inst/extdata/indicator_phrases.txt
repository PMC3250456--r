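investigated
known to
study
evident
identified
significant change
observed
showed
we report
suggest
demonstrated
examined
found that
conclude
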