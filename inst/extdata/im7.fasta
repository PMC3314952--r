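>im7_wild_type colicin E7 immunity protein, 87 residues
MELKNSISDYTEAEFVQLLKEIEKENVAATDDVLDVLLEHFVKITEHPDGTDLIYYPSDN
RDDSPEGIVKEIKEWRAANGKPGFKQG
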