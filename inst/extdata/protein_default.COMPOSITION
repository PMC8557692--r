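# Default protein background composition: database-wide amino-acid
# frequencies of UniProtKB/Swiss-Prot (2021 release statistics), with
# leucine absorbing the 0.0007 rounding remainder so the table sums to 1.
# One residue and one frequency per line; renormalized on load.
# Override with a file of the same format (CLI flag -c).
A 0.0825
C 0.0138
D 0.0546
E 0.0672
F 0.0386
G 0.0708
H 0.0227
I 0.0592
K 0.0580
L 0.0973
M 0.0241
N 0.0406
P 0.0474
Q 0.0393
R 0.0553
S 0.0664
T 0.0535
V 0.0686
W 0.0109
Y 0.0292
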