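alias	canonical
miR-3405p	miR-340-5p
miR21	miR-21
mir-21	miR-21
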