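>MBPSYN_BOVIN synthetic bovine MBP-like fixture (constructed stand-in, not UniProt P02687)
GASVQYHSKEMFKAKSIALRDAQQIRNLNPAGKPFTVIVRAEVKCRIKTLAAYQKQTTVA
LNFRFTTKHVHPRNHWKTAENSMTQDENPVVHFAGAVRFIWSQIFVNVVRGKLLMLSERG
MASANVTIQSIPKLNREQSPAMRVKKCYQTYLATASTMDHARALFQLQIKQFIRIPFHPF
KNKKLLPKVVPGVMHVGQGKRNEGIYYSGAALLKDGRQFNTNEQETETQNGSGRIEAMQR
QKKRVVPERDIRILSIVQRLGEASDTRLELQKTKELSRNITDPQPAEKVMSPINMEGPAY
NNQ
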