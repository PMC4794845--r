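>MBPSYN_HUMAN synthetic human MBP-like fixture (constructed stand-in, not UniProt P02686)
VQYHSKEMFKAKEIALRDAQQIRNLNPAGKPFEVIVRAEVKCRIKTLAAYQKQTTVILNF
RFTTKHVHPRNHWKTAENSMTQDENPVVHFAGAVRFIWSQIFMNVVRGKLLMLSERGMAS
ANVTIQSIPKANREQSPAMRVKKCYQTYLATASTMDHARALFQLQIKQFTRIPFHPFKNK
KLLPKVVPGVMHVGQIKRNEGIYYSGAALLKDGRQFNTNEQCTETQNGSGRIEAMQRQKK
RVVPERDIRILSIVQRLGEASFTRLELQKTKELSRNITDPQPAEKVMSPINMEGLAYNNQ
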