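>LBR_RS_fragment start=72 turkey Lamin B Receptor RS-domain segment (residues 72-87)
PSRRSRSRSRSRSPGR
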