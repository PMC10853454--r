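>PTHR1_SYNTHETIC synthetic stand-in for the human PTHR1 N-terminal region; residues 54-80 at native coordinates, flanks are fixed filler
MGSAHTLNQPGVFYWCDEAISTGHLNPQVSAGTHLNPQVFYWGSTAHLNPQSKEVLQRPA
SIMESDKGWTSASTSGKPRKDKASGHLNPQVTWFYGSTAHLNPQVGSTAHLNPQVGSTAR
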