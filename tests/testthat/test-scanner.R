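test_that("quick scan seeds contigs where a single window is biased", {
  comp <- uniform_protein_comp()
  rec <- seq_record("e15", strrep("E", 15))
  res <- quick_scan(rec, comp, scan_params())
  expect_named(res, "E")
  expect_equal(res$E$start, 1L)
  expect_equal(res$E$end, 15L)
  # restriction removes the residue from consideration entirely
  expect_length(quick_scan(rec, comp, scan_params(restriction = "K")), 0)
  # overlapping kept windows union into one contig
  res30 <- quick_scan(seq_record("e30", strrep("E", 30)), comp,
                      scan_params())
  expect_equal(nrow(res30$E), 1L)
  expect_equal(c(res30$E$start, res30$E$end), c(1L, 30L))
  # too-short sequences yield an empty result, not an error
  expect_length(quick_scan(seq_record("s", "MKLV"), comp, scan_params()), 0)
})

test_that("kept-window fraction on null DNA matches the baseline rate", {
  # Monte-Carlo calibration: on uniform random DNA the per-window
  # keep probability is the binomial tail at the smallest count below
  # the baseline; observed fraction must sit within 3 sigma (binomial,
  # pooled over 12 seeded replicates).
  dna <- dna_alphabet()
  unif <- default_composition(dna)
  params <- scan_params(alphabet = dna)
  lt <- log_binom_tail(0:15, rep(15L, 16L), 0.25)
  kmin <- which(lt < log10(0.001))[1] - 1L
  q <- 10^lt[kmin + 1L]
  L <- 10000L
  starts <- unique(c(seq(1L, L - 14L, by = 3L), L - 14L))
  kept <- 0
  reps <- 12
  for (i in seq_len(reps)) {
    rec <- generate_sequence(L, unif, seed = 5000 + i, id = "null")
    cont <- quick_scan(rec, unif, params)
    kept <- kept + sum(vapply(cont, function(df) {
      sum(df$member_windows)
    }, numeric(1)))
  }
  n <- length(starts) * 4 * reps
  expect_lt(abs(kept / n - q), 3 * sqrt(q * (1 - q) / n))
})

test_that("a pure tract is its own minimizer", {
  comp <- protein_comp_with(E = 0.068)
  rec <- seq_record("e20", strrep("E", 20))
  reg <- minimize_contig(rec, list(start = 1L, end = 20L), "E", comp,
                         scan_params())
  expect_equal(c(reg$start, reg$end), c(1L, 20L))
  expect_equal(reg$logP, 20 * log10(0.068), tolerance = 1e-9)
  expect_identical(reg$kind, "single")
})

test_that("minimization stops where dilution starts", {
  comp <- uniform_protein_comp()
  rec <- seq_record("ka", paste0(strrep("K", 10), strrep("A", 10)))
  reg <- minimize_contig(rec, list(start = 1L, end = 20L), "K", comp,
                         scan_params(m = 5))
  expect_equal(c(reg$start, reg$end), c(1L, 10L))
  expect_equal(reg$logP, 10 * log10(0.05), tolerance = 1e-9)
})

test_that("single-residue optima equal exhaustive subinterval search", {
  comp <- uniform_protein_comp()
  params <- scan_params(precision = "thorough")
  for (seed in 1:12) {
    rec <- generate_sequence(c(80, 100, 120)[1 + seed %% 3],
                             background = comp, seed = 300 + seed,
                             id = "s")
    chars <- strsplit(rec$residues, "", fixed = TRUE)[[1]]
    df <- annotate(rec, comp, params)
    for (r in protein_alphabet()$letters) {
      ob <- oracle_best_region(chars, r, 0.05, params$m, params$M,
                               params$log_t)
      sub <- single_regions_for(df, r)
      if (is.null(ob)) {
        expect_equal(nrow(sub), 0)
      } else {
        # the exhaustive optimum must be among the reported regions
        # (recursive exclusion may add further, disjoint regions whose
        # post-trim tails can even undercut it)
        found <- any(abs(sub$log10p - ob$logP) <= 1e-6 &
                       sub$start == ob$start & sub$end == ob$end)
        expect_true(found)
      }
    }
  }
})

test_that("trimming shears non-contributing ends of minimum-length hits", {
  comp <- uniform_protein_comp()
  rec <- seq_record("t1", paste0("A", strrep("E", 13), "A"))
  df <- annotate(rec, comp, scan_params())
  hit <- single_regions_for(df, "E")
  expect_equal(nrow(hit), 1)
  expect_equal(c(hit$start, hit$end), c(2L, 14L))
  expect_equal(hit$n_biased, 13L)
  expect_equal(hit$log10p, 13 * log10(0.05), tolerance = 1e-9)
  # a region already flush with its bias is a fixed point
  reg <- list(seq_id = "t2", start = 1L, end = 15L, residue_set = "E",
              counts = c(E = 15L), logP = 15 * log10(0.05),
              kind = "single")
  rec2 <- seq_record("t2", strrep("E", 15))
  expect_identical(trim_region(reg, rec2, comp, scan_params()), reg)
})

test_that("overlapping D and E regions merge with pooled p and k", {
  comp <- protein_comp_with(D = 0.055, E = 0.055)
  rec <- seq_record("de", strrep("DE", 8))
  df <- annotate(rec, comp, scan_params())
  multi <- df[df$kind == "multiple", ]
  expect_equal(nrow(multi), 1)
  expect_equal(c(multi$start, multi$end), c(1L, 16L))
  # pooled probability 0.11, all 16 positions successes
  expect_equal(multi$log10p, 16 * log10(0.11), tolerance = 1e-9)
  expect_identical(multi$signature, "{DE}")  # equal precedence, D first
  # the single-residue inputs are retained alongside
  expect_equal(sum(df$kind == "single"), 2)
  expect_lt(multi$log10p, min(df$log10p[df$kind == "single"]))
})

test_that("non-overlapping regions never merge", {
  comp <- uniform_protein_comp()
  rec <- generate_sequence(200, comp,
                           list(implant_spec(20, 20, "Q", 1),
                                implant_spec(120, 20, "E", 1)),
                           seed = 11, id = "two")
  df <- annotate(rec, comp, scan_params())
  expect_equal(sum(df$kind == "multiple"), 0)
  expect_setequal(unlist(df$residue_set), c("Q", "E"))
})

test_that("an implanted tract is recovered as one region", {
  comp <- uniform_protein_comp()
  rec <- generate_sequence(600, comp, list(implant_spec(200, 30, "Q", 1)),
                           seed = 21, id = "imp")
  df <- annotate(rec, comp, scan_params(t = 1e-9))
  q <- single_regions_for(df, "Q")
  expect_equal(nrow(q), 1)
  overlap <- min(q$end, 229) - max(q$start, 200) + 1
  expect_gte(overlap / 30, 0.9)
})

test_that("a restriction list is sound: no output residue outside it", {
  comp <- uniform_protein_comp()
  for (seed in 1:5) {
    rec <- generate_sequence(400, comp,
                             list(implant_spec(50, 25, "Q", 0.9),
                                  implant_spec(200, 25, "K", 0.9)),
                             seed = seed, id = "r")
    df <- annotate(rec, comp,
                   scan_params(precision = "medium",
                               restriction = c("Q", "E")))
    expect_true(all(unlist(df$residue_set) %in% c("Q", "E")))
    expect_true(all(vapply(df$residue_set, function(s) {
      length(s) >= 1
    }, TRUE)))
  }
})

test_that("unknown residues dilute unless -k removes them", {
  comp <- uniform_protein_comp()
  res <- paste0(strrep("Q", 8), "XX", strrep("Q", 8))
  rec <- seq_record("qx", res)
  with_x <- annotate(rec, comp, scan_params())
  no_x <- annotate(rec, comp, scan_params(ignore_unknown = TRUE))
  expect_equal(nrow(with_x), 1)
  expect_equal(nrow(no_x), 1)
  expect_equal(with_x$n_biased, no_x$n_biased)
  # dropping the X's shrinks the window at fixed count: more significant
  expect_lt(no_x$log10p, with_x$log10p)
  expect_equal(no_x$log10p, 16 * log10(0.05), tolerance = 1e-9)
  expect_equal(with_x$log10p, log_binom_tail(16, 18, 0.05),
               tolerance = 1e-12)
  # X can never be a biasing residue
  expect_false("X" %in% unlist(c(with_x$residue_set, no_x$residue_set)))
})

test_that("uniform random sequences are empty at a stringent threshold", {
  comp <- uniform_protein_comp()
  params <- scan_params(t = 1e-9)
  for (seed in 1:20) {
    rec <- generate_sequence(500, comp, seed = 700 + seed, id = "null")
    expect_equal(nrow(annotate(rec, comp, params)), 0)
  }
})

test_that("regions come out sorted by start then P-value", {
  comp <- uniform_protein_comp()
  rec <- generate_sequence(500, comp,
                           list(implant_spec(40, 30, "PQ", 0.95),
                                implant_spec(300, 25, "E", 0.9)),
                           seed = 31, id = "s")
  df <- annotate(rec, comp, scan_params(precision = "thorough"))
  expect_gt(nrow(df), 1)
  expect_true(all(diff(df$start) >= 0))
  same <- which(diff(df$start) == 0)
  expect_true(all(df$log10p[same] <= df$log10p[same + 1L]))
  expect_equal(df$index, seq_len(nrow(df)))
})

test_that("thorough finds at least what fast finds, medium between", {
  comp <- uniform_protein_comp()
  for (seed in 1:4) {
    rec <- generate_sequence(700, comp,
                             list(implant_spec(100, 30, "Q", 0.7),
                                  implant_spec(400, 40, "ED", 0.6)),
                             seed = seed, id = "z")
    n <- vapply(c("fast", "medium", "thorough"), function(z) {
      nrow(annotate(rec, comp, scan_params(precision = z)))
    }, numeric(1))
    expect_lte(n[["fast"]], n[["medium"]])
    expect_lte(n[["medium"]], n[["thorough"]])
  }
})

test_that("strand symmetry: reverse complement mirrors the annotation", {
  dna <- dna_alphabet()
  unif <- default_composition(dna)
  params <- scan_params(precision = "thorough", alphabet = dna)
  L <- 300L
  rec <- generate_sequence(L, unif,
                           list(implant_spec(50, 35, "GT", 0.9),
                                implant_spec(200, 30, "A", 0.9)),
                           seed = 5, id = "fwd")
  rc <- seq_record("rc", revcomp(rec$residues), dna)
  a <- annotate(rec, unif, params)
  b <- annotate(rc, unif, params)
  expect_equal(nrow(a), nrow(b))
  b <- b[order(L - b$end + 1, b$log10p), ]
  expect_equal(a$start, L - b$end + 1L, ignore_attr = TRUE)
  expect_equal(a$end, L - b$start + 1L, ignore_attr = TRUE)
  expect_equal(a$log10p, b$log10p, tolerance = 1e-9, ignore_attr = TRUE)
  for (i in seq_len(nrow(a))) {
    expect_setequal(chartr("ACGT", "TGCA", a$residue_set[[i]]),
                    b$residue_set[[i]])
  }
})
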