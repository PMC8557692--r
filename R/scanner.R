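#' Scan parameters
#'
#' All knobs of the annotation pipeline. The precision mode sets the
#' baseline of the initial quick scan: `fast` keeps length-`m` windows with
#' tail probability below 0.001 and slides in steps of 3 residues;
#' `medium` uses 0.01 and step 2; `thorough` uses 0.1 and step 1. A higher
#' baseline and smaller step store more (and longer) candidate contigs, so
#' subtler, often multi-residue skews survive to the minimization stage —
#' at the cost of runtime and, on large databases, output volume.
#'
#' @param t Output P-value threshold (linear scale; default 1e-3). A region
#'   is reported only if its minimized binomial tail P-value is `<= t`.
#' @param m Minimum window/region length in residues (default 15).
#' @param M Maximum region length considered during minimization (default
#'   500); merged multiple-residue regions may exceed it.
#' @param precision `"fast"`, `"medium"` or `"thorough"`.
#' @param restriction Character vector of residue letters to which the scan
#'   is restricted (CLI `-r`), or `NULL` for all letters.
#' @param ignore_unknown If `TRUE` (CLI `-k`), unknown letters (`X`/`N`)
#'   are dropped from both the count and the window length; if `FALSE`
#'   they still occupy window positions (diluting the bias) but can never
#'   be biasing residues themselves.
#' @param alphabet Alphabet the parameters apply to.
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(t = 1e-3, m = 15L, M = 500L,
                        precision = c("fast", "medium", "thorough"),
                        restriction = NULL, ignore_unknown = FALSE,
                        alphabet = protein_alphabet()) {
  precision <- match.arg(precision)
  if (is.character(alphabet)) alphabet <- get_alphabet(alphabet)
  stopifnot(is_alphabet(alphabet), t > 0, t <= 1)
  m <- as.integer(m)
  M <- as.integer(M)
  if (m < 1L || m > M) stop("need 1 <= m <= M")
  if (!is.null(restriction)) {
    restriction <- unique(toupper(unlist(strsplit(restriction, "",
                                                  fixed = TRUE))))
    bad <- setdiff(restriction, alphabet$letters)
    if (length(bad)) {
      stop("restriction letter(s) outside the ", alphabet$kind,
           " alphabet: ", paste(bad, collapse = ", "))
    }
  }
  mode <- switch(precision,
                 fast = list(P0 = 0.001, step = 3L),
                 medium = list(P0 = 0.01, step = 2L),
                 thorough = list(P0 = 0.1, step = 1L))
  structure(
    list(t = t, log_t = log10(t), m = m, M = M, precision = precision,
         baseline_P0 = mode$P0, step = mode$step,
         restriction = restriction,
         ignore_unknown = isTRUE(ignore_unknown), alphabet = alphabet),
    class = "scan_params"
  )
}

#' @export
print.scan_params <- function(x, ...) {
  cat(sprintf(
    "<scan_params> t=%g m=%d M=%d z=%s (P0=%g, step=%d) r=%s k=%s [%s]\n",
    x$t, x$m, x$M, x$precision, x$baseline_P0, x$step,
    if (is.null(x$restriction)) "-" else paste(x$restriction, collapse = ""),
    if (x$ignore_unknown) "on" else "off", x$alphabet$kind))
  invisible(x)
}

# Shared cache of tail tables keyed by p, so residues with identical
# background probability (e.g. uniform DNA) share tables. Returns a
# handle with $eval(k, w) (the tail_table evaluator) and $vec(w) (the
# whole tail vector for one window length, for direct indexing in the
# minimizer's hot loop).
new_tail_cache <- function() {
  env <- new.env(parent = emptyenv())
  function(p, w_max) {
    key <- sprintf("%.17g", p)
    cur <- if (exists(key, envir = env)) get(key, envir = env) else NULL
    if (is.null(cur)) {
      vecs <- new.env(parent = emptyenv())
      vec <- function(w) {
        kw <- as.character(w)
        v <- vecs[[kw]]
        if (is.null(v)) {
          v <- .log10_tail_vector(w, p)
          vecs[[kw]] <- v
        }
        v
      }
      eval_kw <- function(k, w) {
        if (length(k) != length(w)) {
          n <- max(length(k), length(w))
          k <- rep_len(as.integer(k), n)
          w <- rep_len(as.integer(w), n)
        }
        out <- numeric(length(k))
        for (wu in unique(w)) {
          sel <- which(w == wu)
          out[sel] <- if (wu == 0L) 0 else vec(wu)[k[sel] + 1L]
        }
        out
      }
      cur <- list(eval = eval_kw, vec = vec)
      assign(key, cur, envir = env)
    }
    cur
  }
}

seq_chars <- function(record) strsplit(record$residues, "", fixed = TRUE)[[1]]

#' Quick scan: seed candidate contigs per residue
#'
#' Stage one of the pipeline. Windows of length `m` are placed at offsets
#' 0, step, 2*step, ... plus one window flush with the sequence end (so a
#' step greater than 1 can never skip a terminal bias). A window is kept
#' for residue `r` when its binomial tail probability falls below the
#' precision mode's baseline; overlapping or bookended kept windows are
#' unioned into candidate contigs.
#'
#' @param record A [seq_record()].
#' @param comp Background [composition_table()].
#' @param params [scan_params()].
#' @return Named list, one entry per residue with at least one contig; each
#'   entry a data.frame with columns `start`, `end`, `member_windows`.
#' @export
quick_scan <- function(record, comp, params = scan_params()) {
  stopifnot(inherits(record, "seq_record"),
            inherits(comp, "composition_table"),
            inherits(params, "scan_params"))
  if (record$alphabet$kind != params$alphabet$kind ||
      record$alphabet$kind != comp$alphabet$kind) {
    stop("record, composition and parameters must share one alphabet")
  }
  chars <- seq_chars(record)
  L <- length(chars)
  m <- params$m
  out <- list()
  if (L < m) return(out)
  starts <- unique(c(seq.int(1L, L - m + 1L, by = params$step), L - m + 1L))
  cum_u <- c(0L, cumsum(chars == record$alphabet$unknown))
  w_eff <- if (params$ignore_unknown) {
    m - (cum_u[starts + m] - cum_u[starts])
  } else {
    rep.int(m, length(starts))
  }
  log_p0 <- log10(params$baseline_P0)
  scan_set <- if (is.null(params$restriction)) params$alphabet$letters
              else params$restriction
  for (r in scan_set) {
    p <- unname(comp$freq[r])
    if (!is.finite(p) || p <= 0 || p >= 1) next  # residue untestable
    kmin <- .min_count_table(m, p, log_p0)
    cum_x <- c(0L, cumsum(chars == r))
    k <- cum_x[starts + m] - cum_x[starts]
    keep <- w_eff >= 1L & !is.na(kmin[pmax(w_eff, 1L)]) &
      k >= kmin[pmax(w_eff, 1L)]
    if (!any(keep)) next
    ks <- sort(starts[keep])
    contig_start <- ks[1L]
    contig_end <- ks[1L] + m - 1L
    nw <- 1L
    rows <- list()
    if (length(ks) > 1L) {
      for (s in ks[-1L]) {
        if (s <= contig_end + 1L) {
          contig_end <- max(contig_end, s + m - 1L)
          nw <- nw + 1L
        } else {
          rows[[length(rows) + 1L]] <- c(contig_start, contig_end, nw)
          contig_start <- s
          contig_end <- s + m - 1L
          nw <- 1L
        }
      }
    }
    rows[[length(rows) + 1L]] <- c(contig_start, contig_end, nw)
    mat <- do.call(rbind, rows)
    out[[r]] <- data.frame(start = mat[, 1L], end = mat[, 2L],
                           member_windows = mat[, 3L])
  }
  out
}

# Exhaustive minimization of the binomial tail over subintervals of
# [s0, e0] for the position mask behind `x_cum` (cumulative counts of the
# residue/set), lengths len_min..len_max. Ties on the untrimmed tail:
# lowest logP, then longest, then leftmost. The argmin is then trimmed
# (ends outside the biasing set sheared off, which can only happen for
# minimum-length optima) and its tail recomputed on the shorter window.
# Returns list(start, end, k, w, logP, raw_start, raw_end) or NULL; logP
# and start/end are post-trim, raw_* the untrimmed argmin extent.
.minimize_span <- function(x_cum, u_cum, s0, e0, len_min, len_max, tails,
                           ignore_unknown) {
  span <- e0 - s0 + 1L
  len_max <- min(len_max, span)
  if (len_max < len_min) return(NULL)
  best_lp <- 0
  cand_i <- integer()
  cand_len <- integer()
  for (len in len_min:len_max) {
    i <- s0:(e0 - len + 1L)
    k <- x_cum[i + len] - x_cum[i]
    if (ignore_unknown) {
      w <- len - (u_cum[i + len] - u_cum[i])
      ok <- w >= 1L
      lp <- numeric(length(i))
      lp[ok] <- tails$eval(k[ok], w[ok])
    } else {
      lp <- tails$vec(len)[k + 1L]
    }
    mn <- min(lp)
    if (mn < best_lp) {
      best_lp <- mn
      sel <- which(lp == mn)
      cand_i <- i[sel]
      cand_len <- rep.int(len, length(sel))
    } else if (mn == best_lp && length(cand_i) <= 2000L) {
      sel <- which(lp == mn)  # exact ties; trimming decides below
      cand_i <- c(cand_i, i[sel])
      cand_len <- c(cand_len, rep.int(len, length(sel)))
    }
  }
  if (best_lp >= 0) return(NULL)
  # among raw-tail ties: best trimmed tail, then longest, then leftmost.
  # The trim rule (shear ends outside the biasing set, recompute on the
  # shorter window) only bites for minimum-length optima; deciding ties
  # on the post-trim tail keeps the outcome independent of scan
  # direction, which strand symmetry on DNA requires.
  n_c <- length(cand_i)
  t_s <- integer(n_c)
  t_e <- integer(n_c)
  t_w <- integer(n_c)
  t_k <- integer(n_c)
  t_lp <- numeric(n_c)
  for (ci in seq_len(n_c)) {
    s <- cand_i[ci]
    e <- cand_i[ci] + cand_len[ci] - 1L
    k <- x_cum[e + 1L] - x_cum[s]
    while (s < e && x_cum[s + 1L] == x_cum[s]) s <- s + 1L
    while (e > s && x_cum[e + 1L] == x_cum[e]) e <- e - 1L
    w <- e - s + 1L
    if (ignore_unknown) w <- w - (u_cum[e + 1L] - u_cum[s])
    t_s[ci] <- s
    t_e[ci] <- e
    t_k[ci] <- k
    t_w[ci] <- w
    t_lp[ci] <- if (w < 1L || k > w) 0 else tails$eval(k, w)
  }
  j <- order(t_lp, -cand_len, cand_i)[1L]
  list(start = t_s[j], end = t_e[j], k = t_k[j], w = t_w[j],
       logP = t_lp[j], raw_start = cand_i[j],
       raw_end = cand_i[j] + cand_len[j] - 1L)
}

# Recursive exclusion: report the best subinterval of [s0, e0], then
# search the flanking segments for further, disjoint regions. The first
# region found is therefore exactly the exhaustive-search optimum of the
# span, and separate tracts of the same residue are all reported.
.minimize_span_multi <- function(x_cum, u_cum, s0, e0, len_min, len_max,
                                 tails, ignore_unknown, log_t) {
  if (e0 - s0 + 1L < len_min) return(list())
  best <- .minimize_span(x_cum, u_cum, s0, e0, len_min, len_max, tails,
                         ignore_unknown)
  if (is.null(best) || best$logP > log_t) return(list())
  c(list(best),
    .minimize_span_multi(x_cum, u_cum, s0, best$raw_start - 1L, len_min,
                         len_max, tails, ignore_unknown, log_t),
    .minimize_span_multi(x_cum, u_cum, best$raw_end + 1L, e0, len_min,
                         len_max, tails, ignore_unknown, log_t))
}

#' Minimize a candidate contig to its best biased region
#'
#' Stage two. Among all subintervals of the contig with length in
#' `[m, M]`, finds the one with the smallest binomial tail probability for
#' the contig's residue. Exact ties on the raw tail resolve to the
#' candidate whose post-trim tail is lowest, then the longest interval,
#' then the leftmost — deterministic and mirror-invariant. The returned
#' region is trimmed, and the output threshold `t` applies to the trimmed
#' tail; `NULL` when even the best subinterval fails it.
#'
#' @param record A [seq_record()].
#' @param contig One row of a [quick_scan()] result (list/row with `start`,
#'   `end`).
#' @param residue The contig's residue letter.
#' @param comp Background composition.
#' @param params [scan_params()].
#' @param tail_cache Optional shared evaluator cache from an enclosing
#'   [annotate()] call.
#' @return A single-residue region (list with `seq_id`, `start`, `end`,
#'   `residue_set`, `counts`, `logP`, `kind`) or `NULL`.
#' @export
minimize_contig <- function(record, contig, residue, comp,
                            params = scan_params(), tail_cache = NULL) {
  chars <- seq_chars(record)
  if (is.null(tail_cache)) tail_cache <- new_tail_cache()
  p <- unname(comp$freq[residue])
  span <- contig$end - contig$start + 1L
  tails <- tail_cache(p, min(params$M, span))
  x_cum <- c(0L, cumsum(chars == residue))
  u_cum <- c(0L, cumsum(chars == record$alphabet$unknown))
  best <- .minimize_span(x_cum, u_cum, as.integer(contig$start),
                         as.integer(contig$end), params$m, params$M,
                         tails, params$ignore_unknown)
  if (is.null(best) || best$logP > params$log_t) return(NULL)
  .make_single_region(record, residue, best, comp, params)
}

.make_single_region <- function(record, residue, best, comp, params) {
  region <- list(seq_id = record$id, start = best$start, end = best$end,
                 residue_set = residue,
                 counts = stats::setNames(best$k, residue),
                 logP = best$logP, kind = "single")
  trim_region(region, record, comp, params)
}

#' Trim non-contributing residues off region ends
#'
#' A minimum-length region can be forced to carry flanking residues that do
#' not belong to its biasing set (the window cannot shrink below `m` during
#' minimization). Trimming shears such residues off both ends, leaving the
#' counts untouched while the window shrinks, so the recomputed tail
#' probability can only fall. Longer regions are already flush (an
#' unconstrained minimizer would have dropped a non-contributing end), so
#' trimming is a no-op for them.
#'
#' @param region A region produced by [minimize_contig()] or
#'   [merge_regions()].
#' @param record Its [seq_record()].
#' @param comp,params Needed to recompute the tail probability.
#' @return The (possibly shortened) region.
#' @export
trim_region <- function(region, record, comp, params = scan_params()) {
  chars <- seq_chars(record)
  s <- region$start
  e <- region$end
  in_set <- chars %in% region$residue_set
  while (s < e && !in_set[s]) s <- s + 1L
  while (e > s && !in_set[e]) e <- e - 1L
  if (s == region$start && e == region$end) return(region)
  region$start <- s
  region$end <- e
  w <- e - s + 1L
  if (params$ignore_unknown) {
    w <- w - sum(chars[s:e] == record$alphabet$unknown)
  }
  p <- sum(comp$freq[region$residue_set])
  k <- sum(region$counts)
  region$logP <- log_binom_tail(k, w, p)
  region
}

#' Merge overlapping single-residue regions into multiple-residue regions
#'
#' Stage three. Single-residue regions that overlap by at least one
#' position are grouped (transitively); each group's pooled residue set is
#' re-minimized over the union extent, with pooled success probability
#' `sum(freq[set])` and pooled counts. The joint region is emitted when its
#' tail probability passes the output threshold; the single-residue inputs
#' are always retained alongside. The biasing residues are ordered by bias
#' precedence: ascending single-residue tail probability within the merged
#' extent, ties alphabetical. Because the merge extent is the union of
#' regions, a merged region may exceed `M`.
#'
#' @param regions List of single-residue regions on one sequence.
#' @param record,comp,params As elsewhere.
#' @param tail_cache Optional shared evaluator cache.
#' @return List of multiple-residue regions (possibly empty).
#' @export
merge_regions <- function(regions, record, comp, params = scan_params(),
                          tail_cache = NULL) {
  if (length(regions) < 2L) return(list())
  if (is.null(tail_cache)) tail_cache <- new_tail_cache()
  ord <- order(vapply(regions, `[[`, numeric(1), "start"))
  regions <- regions[ord]
  starts <- vapply(regions, `[[`, numeric(1), "start")
  ends <- vapply(regions, `[[`, numeric(1), "end")
  groups <- list()
  cur <- 1L
  cur_end <- ends[1L]
  if (length(regions) > 1L) {
    for (i in 2L:length(regions)) {
      if (starts[i] <= cur_end) {  # >= 1 shared position
        cur <- c(cur, i)
        cur_end <- max(cur_end, ends[i])
      } else {
        groups[[length(groups) + 1L]] <- cur
        cur <- i
        cur_end <- ends[i]
      }
    }
  }
  groups[[length(groups) + 1L]] <- cur
  chars <- seq_chars(record)
  u_cum <- c(0L, cumsum(chars == record$alphabet$unknown))
  out <- list()
  for (g in groups) {
    if (length(g) < 2L) next
    set <- sort(unique(unlist(lapply(regions[g], `[[`, "residue_set"))))
    if (length(set) < 2L) next
    gs <- min(starts[g])
    ge <- max(ends[g])
    p_pool <- sum(comp$freq[set])
    if (p_pool <= 0 || p_pool >= 1) next
    x_cum <- c(0L, cumsum(chars %in% set))
    tails <- tail_cache(p_pool, ge - gs + 1L)
    best <- .minimize_span(x_cum, u_cum, gs, ge, params$m, ge - gs + 1L,
                           tails, params$ignore_unknown)
    if (is.null(best) || best$logP > params$log_t) next
    counts <- vapply(set, function(r) {
      sum(chars[best$start:best$end] == r)
    }, integer(1))
    region <- list(seq_id = record$id, start = best$start, end = best$end,
                   residue_set = set, counts = counts,
                   logP = best$logP, kind = "multiple")
    region <- trim_region(region, record, comp, params)
    region <- order_precedence(region, record, comp, params)
    out[[length(out) + 1L]] <- region
  }
  out
}

# Bias precedence: ascending single-residue tail probability within the
# region's extent; ties alphabetical (the set is pre-sorted, and R's
# order() is stable).
order_precedence <- function(region, record, comp, params) {
  if (length(region$residue_set) < 2L) return(region)
  chars <- seq_chars(record)
  w <- region$end - region$start + 1L
  if (params$ignore_unknown) {
    w <- w - sum(chars[region$start:region$end] == record$alphabet$unknown)
  }
  lp <- vapply(region$residue_set, function(r) {
    p <- unname(comp$freq[r])
    if (!is.finite(p) || p <= 0 || p >= 1) return(0)
    log_binom_tail(min(region$counts[[r]], w), w, p)
  }, numeric(1))
  ord <- order(lp)
  region$residue_set <- region$residue_set[ord]
  region$counts <- region$counts[region$residue_set]
  region
}

#' Annotate a sequence with compositionally biased regions
#'
#' The full pipeline: quick scan, per-contig minimization, merging of
#' overlapping single-residue regions, and trimming. Returns every
#' single- and multiple-residue region passing the output threshold,
#' sorted by start position then tail probability.
#'
#' @param record A [seq_record()].
#' @param comp Background composition; defaults to
#'   [default_composition()] for the record's alphabet.
#' @param params [scan_params()]; defaults match the record's alphabet.
#' @return A data.frame of class `lps_regions` with one row per region:
#'   `seq_id`, `index`, `kind`, `start`, `end`, `n_biased` (residues of the
#'   biasing set inside the region), `length`, `log10p`, `signature`,
#'   `bias_class`, `enrichment`, plus list columns `residue_set`, `counts`
#'   and `excluded` (excised-domain gaps after [remap_regions()]).
#' @examples
#' rec <- seq_record("toy", paste(c(rep("Q", 30), rep("A", 30)),
#'                   collapse = ""))
#' annotate(rec, params = scan_params(m = 15))
#' @export
annotate <- function(record, comp = NULL, params = NULL) {
  if (is.null(params)) params <- scan_params(alphabet = record$alphabet)
  if (is.null(comp)) comp <- default_composition(record$alphabet)
  cache <- new_tail_cache()
  chars <- seq_chars(record)
  L <- length(chars)
  u_cum <- c(0L, cumsum(chars == record$alphabet$unknown))
  singles <- list()
  # The quick scan decides which residues earn minimization effort: a
  # residue with no window below the mode's baseline is never pursued, so
  # a higher baseline (thorough) admits more residues. Minimization itself
  # always honours the brute-force contract — the best subinterval of the
  # whole sequence, then recursive exclusion for further disjoint tracts —
  # so found regions do not depend on how kept windows happened to chain
  # into contigs.
  contigs <- quick_scan(record, comp, params)
  for (r in names(contigs)) {
    p <- unname(comp$freq[r])
    tails <- cache(p, min(params$M, L))
    x_cum <- c(0L, cumsum(chars == r))
    bests <- .minimize_span_multi(x_cum, u_cum, 1L, L, params$m,
                                  params$M, tails, params$ignore_unknown,
                                  params$log_t)
    for (b in bests) {
      singles[[length(singles) + 1L]] <-
        .make_single_region(record, r, b, comp, params)
    }
  }
  multiples <- merge_regions(singles, record, comp, params,
                             tail_cache = cache)
  regions_to_df(c(singles, multiples), record, comp, params)
}

#' @rdname annotate
#' @param records List of [seq_record()]s (or a single one).
#' @export
annotate_fasta <- function(records, comp = NULL, params = NULL) {
  if (inherits(records, "seq_record")) records <- list(records)
  res <- lapply(records, annotate, comp = comp, params = params)
  out <- do.call(rbind, res)
  if (is.null(out)) out <- regions_to_df(list(), NULL, NULL, NULL)
  class(out) <- c("lps_regions", "data.frame")
  out
}

# Assemble the user-facing region table; sorting and indexing happen here.
regions_to_df <- function(regions, record, comp, params) {
  if (!length(regions)) {
    df <- data.frame(seq_id = character(), index = integer(),
                     kind = character(), start = integer(),
                     end = integer(), n_biased = integer(),
                     length = integer(), log10p = numeric(),
                     signature = character(), bias_class = character(),
                     enrichment = numeric(), stringsAsFactors = FALSE)
    df$residue_set <- list()
    df$counts <- list()
    df$excluded <- list()
    class(df) <- c("lps_regions", "data.frame")
    return(df)
  }
  ord <- order(vapply(regions, `[[`, numeric(1), "start"),
               vapply(regions, `[[`, numeric(1), "logP"))
  regions <- regions[ord]
  kind_tab <- vapply(regions, `[[`, "", "kind")
  df <- data.frame(
    seq_id = vapply(regions, `[[`, "", "seq_id"),
    index = seq_along(regions),
    kind = kind_tab,
    start = vapply(regions, function(r) as.integer(r$start), integer(1)),
    end = vapply(regions, function(r) as.integer(r$end), integer(1)),
    n_biased = vapply(regions, function(r) as.integer(sum(r$counts)),
                      integer(1)),
    length = vapply(regions, function(r) {
      as.integer(r$end - r$start + 1L)
    }, integer(1)),
    log10p = vapply(regions, `[[`, numeric(1), "logP"),
    stringsAsFactors = FALSE
  )
  df$signature <- vapply(regions, function(r) {
    bias_signature(r$residue_set)
  }, "")
  df$bias_class <- vapply(regions, function(r) {
    if (is.null(comp)) return("mixed")
    if (comp$alphabet$kind == "dna") dna_class(r$residue_set)
    else protein_class(r$residue_set)
  }, "")
  df$enrichment <- vapply(regions, function(r) {
    if (is.null(comp)) return(NA_real_)
    bias_enrichment(sum(r$counts), r$end - r$start + 1L,
                    sum(comp$freq[r$residue_set]))
  }, numeric(1))
  df$residue_set <- lapply(regions, `[[`, "residue_set")
  df$counts <- lapply(regions, `[[`, "counts")
  df$excluded <- lapply(regions, function(r) {
    if (is.null(r$excluded)) empty_intervals() else r$excluded
  })
  rownames(df) <- NULL
  class(df) <- c("lps_regions", "data.frame")
  df
}

#' @export
print.lps_regions <- function(x, ...) {
  cat(sprintf("<lps_regions> %d region(s)\n", nrow(x)))
  cols <- c("seq_id", "kind", "start", "end", "n_biased",
            "log10p", "signature", "bias_class", "enrichment")
  if (!all(cols %in% names(x))) {
    print.data.frame(x)
    return(invisible(x))
  }
  if (nrow(x)) {
    show <- x[, cols]
    show$log10p <- signif(show$log10p, 4)
    show$enrichment <- round(show$enrichment, 2)
    print.data.frame(utils::head(show, 20))
    if (nrow(x) > 20) cat("... and", nrow(x) - 20L, "more\n")
  }
  invisible(x)
}
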