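# Shared fixtures and independent oracles. The binomial oracle is R's
# pbinom (a different code path from the package's log-add summation); the
# region oracle is a literal exhaustive subinterval search built on it.

uniform_protein_comp <- function() {
  a <- protein_alphabet()
  composition_table(a, stats::setNames(rep(0.05, 20), a$letters),
                    source = "uniform protein")
}

protein_comp_with <- function(...) {
  # e.g. protein_comp_with(E = 0.068): named residues get the given
  # frequencies, the rest share the remainder equally
  a <- protein_alphabet()
  fixed <- c(...)
  rest <- setdiff(a$letters, names(fixed))
  freq <- stats::setNames(rep((1 - sum(fixed)) / length(rest),
                              length(rest)), rest)
  composition_table(a, c(fixed, freq), source = "test")
}

oracle_tail <- function(k, w, p) {
  stats::pbinom(k - 1, w, p, lower.tail = FALSE, log.p = TRUE) / log(10)
}

# Exhaustive single-residue optimum over all subintervals with length in
# [m, M]: collect every untrimmed argmin of the raw tail, apply the trim
# rule to each, then pick the best trimmed tail (ties: longest interval,
# then leftmost), then apply the output threshold.
oracle_best_region <- function(chars, r, p, m, M, log_t) {
  L <- length(chars)
  if (L < m) return(NULL)
  cs <- c(0L, cumsum(chars == r))
  best_lp <- Inf
  cand_i <- integer()
  cand_len <- integer()
  for (len in m:min(M, L)) {
    i <- 1:(L - len + 1L)
    k <- cs[i + len] - cs[i]
    lp <- oracle_tail(k, len, p)
    mn <- min(lp)
    if (mn < best_lp) {
      best_lp <- mn
      sel <- which(lp == mn)
      cand_i <- i[sel]
      cand_len <- rep.int(len, length(sel))
    } else if (mn == best_lp) {
      sel <- which(lp == mn)
      cand_i <- c(cand_i, i[sel])
      cand_len <- c(cand_len, rep.int(len, length(sel)))
    }
  }
  if (!is.finite(best_lp) || best_lp >= 0) return(NULL)
  n_c <- length(cand_i)
  t_s <- integer(n_c)
  t_e <- integer(n_c)
  t_lp <- numeric(n_c)
  t_k <- integer(n_c)
  for (ci in seq_len(n_c)) {
    s <- cand_i[ci]
    e <- cand_i[ci] + cand_len[ci] - 1L
    k <- cs[e + 1L] - cs[s]
    while (s < e && chars[s] != r) s <- s + 1L
    while (e > s && chars[e] != r) e <- e - 1L
    t_s[ci] <- s
    t_e[ci] <- e
    t_k[ci] <- k
    t_lp[ci] <- oracle_tail(k, e - s + 1L, p)
  }
  j <- order(t_lp, -cand_len, cand_i)[1L]
  if (t_lp[j] > log_t) return(NULL)
  list(start = t_s[j], end = t_e[j], logP = t_lp[j], k = t_k[j])
}

revcomp <- function(s) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(s, "", fixed = TRUE)[[1]])),
        collapse = "")
}

region_residue <- function(df, i) df$residue_set[[i]]

single_regions_for <- function(df, r) {
  df[df$kind == "single" &
       vapply(df$residue_set, function(s) identical(s, r), TRUE), ,
     drop = FALSE]
}
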