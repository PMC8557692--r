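# flpsr

Annotation of compositionally biased (CB) regions — from concentrated
"low-complexity" tracts to long, mild skews — in protein and DNA
sequences, by binomial P-value minimization.

## The problem and the statistic

Many proteins carry tracts enriched for a subset of residue types:
poly-glutamine runs, serine/arginine-rich stretches, acidic blocks,
prion-like glutamine/asparagine domains. These regions are strongly tied
to intrinsic disorder, condensate formation and the uncharacterized "dark
matter" of the protein universe, and DNA shows the analogous base-
composition skews. `flpsr` finds such regions as *low-probability
subsequences*: for a window of length `w` containing `k` copies of a
residue whose background frequency is `p`, the score is the binomial tail

    P = sum_{i=k..w} C(w, i) p^i (1 - p)^(w - i)

carried in log10 throughout (proteome-scale scans produce P-values far
below double-precision underflow). The pipeline per sequence:

1. **Quick scan** — windows of length `m` slide at the precision mode's
   step; windows whose tail probability beats the mode's baseline
   (`fast` 0.001/step 3, `medium` 0.01/step 2, `thorough` 0.1/step 1)
   chain into candidate contigs and decide which residues are pursued.
2. **Minimize** — for each pursued residue, the subinterval with length
   in `[m, M]` minimizing the tail probability is located (exhaustively;
   further disjoint tracts are found by recursing on the flanks).
3. **Merge** — overlapping single-residue regions are re-minimized
   jointly with pooled counts and pooled background probability, giving
   multiple-residue regions such as `{PYQ}`.
4. **Trim + output** — minimum-length regions are sheared of
   non-contributing ends; everything below the output threshold `t` is
   reported with its bias signature (`{KR}`), physico-chemical bias class
   (protein: Taylor-Venn-derived labels; DNA: the eight strand-paired
   classes such as `{AC}—{GT}`), and enrichment.

Accessories mirror the classic tool chain: a composition maker
(background frequencies from any FASTA), a domain filter that excises or
masks annotated domains so *discontinuous* CB regions can be found (with
coordinate remapping back to the original sequence), restriction lists,
and an fLPS-style command line with `long`, `short` and `oneline` output.

## Worked example

```r
library(flpsr)

# a 600-residue random background with one glutamine-rich implant
comp <- composition_table(protein_alphabet(),
                          setNames(rep(0.05, 20), protein_alphabet()$letters),
                          source = "uniform")
rec <- generate_sequence(600, comp,
                         list(implant_spec(200, 30, "Q", 1)),
                         seed = 21, id = "imp")
annotate(rec, comp, scan_params(t = 1e-9))
#> <lps_regions> 1 region(s)
#>   seq_id   kind start end n_biased log10p signature bias_class enrichment
#> 1    imp single   200 229       30 -39.03 {Q}       glx        20
```

One `{Q}` region covering exactly the implanted tract: 30 glutamines in a
30-residue window where each position had background probability 0.05,
so log10 P = 30·log10(0.05) ≈ −39.03. Enrichment 20 = (30/30)/0.05: the
tract is 20-fold enriched over background, and `glx` is the smallest
packaged physico-chemical class containing `{Q}`. The same call on DNA
(`scan_params(alphabet = dna_alphabet())`, uniform base background by
default) labels regions with the eight DNA bias classes.

Command line, as in the original tool chain:

```r
run_flps(c("-t1e-5", "-m5", "-M25", "-o", "long", "yeast.fasta"))
run_flps(c("-z", "thorough", "-t0.001", "-M", "1000", "yeast.fasta"))
run_composition_maker("yeast.fasta")          # yeast.fasta.COMPOSITION
run_domain_filter(c("-D", "excised", "domains.tsv", "yeast.fasta"))
run_flps(c("-dn", "DNA.example.fasta"))       # DNA mode with headers
```

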