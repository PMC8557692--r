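# Physico-chemical bias classes for protein residue sets, built on the
# Taylor Venn diagram of amino-acid properties plus the extra intersection
# categories used for bias labelling (glx, tiny_polar, polar_aromatic).
# Format: label <whitespace> residue letters. A region's class is the
# listed class with the SMALLEST membership whose residue set contains all
# of the region's biasing residues; ties break by file order; no container
# means class "mixed". User-replaceable via protein_class(table = ...).
negative       DE
glx            EQ
tiny_polar     CS
positive       HKR
aliphatic      ILV
polar_aromatic HWY
tiny           ACGS
aromatic       FHWY
charged        DEHKR
small          ACDGNPSTV
polar          CDEHKNQRSTWY
hydrophobic    ACFGHIKLMTVWY
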