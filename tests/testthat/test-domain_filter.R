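make_filter_record <- function(n = 100, seed = 41) {
  generate_sequence(n, uniform_protein_comp(), seed = seed, id = "p1")
}

test_that("excision shortens, masking preserves length", {
  rec <- make_filter_record()
  dom <- data.frame(start = 21L, end = 50L, domain_id = "PF00076")
  ex <- apply_domain_filter(rec, dom, "excised")
  expect_equal(nchar(ex$residues), 70)
  expect_identical(ex$filtered_intervals$start, 21L)
  expect_identical(ex$filtered_intervals$end, 50L)
  orig <- strsplit(rec$residues, "")[[1]]
  expect_identical(ex$residues, paste(orig[-(21:50)], collapse = ""))

  mk <- apply_domain_filter(rec, dom, "masked")
  expect_equal(nchar(mk$residues), 100)
  masked <- strsplit(mk$residues, "")[[1]]
  expect_true(all(masked[21:50] == "X"))
  expect_identical(masked[-(21:50)], orig[-(21:50)])
})

test_that("overlapping domains are merged before filtering", {
  rec <- make_filter_record()
  dom <- data.frame(start = c(10L, 25L), end = c(30L, 40L),
                    domain_id = c("d1", "d2"))
  ex <- apply_domain_filter(rec, dom, "excised")
  expect_equal(nrow(ex$filtered_intervals), 1)
  expect_equal(c(ex$filtered_intervals$start, ex$filtered_intervals$end),
               c(10L, 40L))
  expect_equal(nchar(ex$residues), 100 - 31)
})

test_that("intervals outside the sequence are rejected by name", {
  rec <- make_filter_record()
  expect_error(apply_domain_filter(rec, data.frame(start = 95, end = 105)),
               "95-105.*p1|p1.*95-105")
})

test_that("remapping restores original coordinates around excisions", {
  rec <- make_filter_record()
  ex <- apply_domain_filter(rec,
                            data.frame(start = 21L, end = 50L,
                                       domain_id = "PF00076"), "excised")
  # independent oracle: enumerate surviving original positions
  kept <- setdiff(1:100, 21:50)
  reg <- list(seq_id = "p1", start = 15L, end = 25L, residue_set = "E",
              counts = c(E = 7L), logP = -5, kind = "single")
  out <- remap_region(reg, ex)
  expect_equal(out$start, kept[15])
  expect_equal(out$end, kept[25])
  expect_equal(c(out$start, out$end), c(15L, 55L))
  expect_equal(nrow(out$excluded), 1)
  expect_equal(c(out$excluded$start, out$excluded$end), c(21L, 50L))
  # a region entirely before the excised span is untouched
  before <- remap_region(list(start = 2L, end = 12L), ex)
  expect_equal(c(before$start, before$end), c(2L, 12L))
  expect_equal(nrow(before$excluded), 0)
})

test_that("excise+scan+remap attributes exactly the original positions", {
  comp <- uniform_protein_comp()
  # implant an E tract whose middle will be excised as a "domain"
  rec <- generate_sequence(160, comp, list(implant_spec(40, 60, "E", 1)),
                           seed = 51, id = "dom")
  dom <- data.frame(seq_id = "dom", start = 60L, end = 79L,
                    domain_id = "PF1")
  ex <- apply_domain_filter(rec, dom, "excised")
  df <- annotate(ex, comp, scan_params(t = 1e-6))
  df <- remap_regions(df, ex)
  e_reg <- single_regions_for(df, "E")
  expect_equal(nrow(e_reg), 1)
  # position-set oracle: biasing positions claimed in original coordinates
  kept <- setdiff(seq_len(160), 60:79)
  orig <- strsplit(rec$residues, "")[[1]]
  claimed <- setdiff(e_reg$start:e_reg$end, 60:79)
  claimed_e <- claimed[orig[claimed] == "E"]
  # versus scanning the concatenated non-domain sequence directly
  direct <- annotate(seq_record("c", paste(orig[kept], collapse = "")),
                     comp, scan_params(t = 1e-6))
  direct_e <- single_regions_for(direct, "E")
  direct_pos <- kept[direct_e$start:direct_e$end]
  direct_pos_e <- direct_pos[orig[direct_pos] == "E"]
  expect_identical(claimed_e, direct_pos_e)
  expect_equal(e_reg$n_biased, length(direct_pos_e))
  expect_equal(e_reg$log10p, direct_e$log10p)
  # the excised span is flagged on the discontinuous region
  expect_equal(nrow(e_reg$excluded[[1]]), 1)
})

test_that("masked scanning with -k matches excised away from domains", {
  comp <- uniform_protein_comp()
  rec <- generate_sequence(200, comp, list(implant_spec(120, 30, "Q", 1)),
                           seed = 61, id = "mk")
  dom <- data.frame(start = 20L, end = 49L, domain_id = "d")
  masked <- apply_domain_filter(rec, dom, "masked")
  excised <- apply_domain_filter(rec, dom, "excised")
  a <- annotate(masked, comp, scan_params(ignore_unknown = TRUE))
  b <- annotate(excised, comp, scan_params())
  expect_setequal(vapply(a$residue_set, paste, "", collapse = ""),
                  vapply(b$residue_set, paste, "", collapse = ""))
})

test_that("domain tables parse and the CLI round-trips through FASTA", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# domains", "p1\t21\t50\tPF00076", "p2\t5\t10\t."), tsv)
  dom <- read_domain_table(tsv)
  expect_equal(nrow(dom), 2)
  expect_identical(dom$seq_id, c("p1", "p2"))
  expect_identical(dom$domain_id[1], "PF00076")

  rec <- make_filter_record()
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(rec, fa)
  out <- withr::local_tempfile(fileext = ".fa")
  status <- run_domain_filter(c("-D", "excised", tsv, fa), out = out)
  expect_equal(status, 0L)
  back <- read_fasta(out, "protein")
  expect_equal(nchar(back[[1]]$residues), 70)
  expect_equal(back[[1]]$filtered_intervals$domain_id, "PF00076")
  # bad usage fails loudly but returns a status instead of stopping
  expect_equal(suppressMessages(run_domain_filter(c(tsv, fa))), 2L)
})
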