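# Independent oracles used by the unit and acceptance tests. These
# deliberately share no code with the package implementation.

# ---- quadruplex grammar oracle -------------------------------------------
# Exhaustive match-existence per anchor via logical dynamic programming on
# the positions: a window-"any" reachability computation, no regular
# expressions involved.
oracle_quadruplex_starts <- function(seq, k) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  if (n < 4 * k + 3) return(integer(0))
  isg <- s == "G"
  cs <- cumsum(c(0L, isg))
  # run_k[p]: TRUE when >= k Gs start at 0-based position p
  run_k <- (cs[(k + 1):(n + 1)] - cs[1:(n - k + 1)]) == k
  run_k <- c(run_k, rep(FALSE, k - 1))
  # any_in_window[p]: any(x[p + k + 1 .. p + k + 7]) for 0-based p
  window_any <- function(x) {
    vapply(seq_len(n) - 1L, function(p) {
      lo <- p + k + 1L; hi <- min(p + k + 7L, n - 1L)
      lo <= hi && any(x[(lo:hi) + 1L])
    }, logical(1))
  }
  m1 <- run_k                       # final run
  m2 <- run_k & window_any(m1)      # run + loop + final run
  m3 <- run_k & window_any(m2)      # run + loop + run + loop + final run
  # maximal G-runs
  r <- rle(isg)
  ends <- cumsum(r$lengths)
  starts0 <- c(0L, head(ends, -1))
  runs <- data.frame(start = starts0[r$values], len = r$lengths[r$values])
  runs <- runs[runs$len >= k, , drop = FALSE]
  hits <- vapply(seq_len(nrow(runs)), function(i) {
    a <- runs$start[i]; L <- runs$len[i]
    # elastic first run: the second run may start anywhere in
    # (a + k, a + L + 7]
    q <- (a + k + 1L):min(a + L + 7L, n - 1L)
    q <- q[q >= 0 & q <= n - 1L]
    length(q) > 0 && any(m3[q + 1L])
  }, logical(1))
  runs$start[hits]
}

# recursive grammar validator for a reported match string: first run
# elastic, three loops of 1-7 arbitrary characters, internal/final runs of
# exactly k Gs
oracle_validate_match <- function(match, k) {
  n <- nchar(match)
  ch <- strsplit(match, "")[[1]]
  grun <- function(from, len) from + len - 1 <= n && all(ch[from:(from + len - 1)] == "G")
  for (r in k:n) {
    if (!grun(1, r)) break
    for (l1 in 1:7) for (l2 in 1:7) for (l3 in 1:7) {
      p2 <- 1 + r + l1
      p3 <- p2 + k + l2
      p4 <- p3 + k + l3
      if (p4 + k - 1 == n && grun(p2, k) && grun(p3, k) && grun(p4, k)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# ---- folding oracles ------------------------------------------------------
oracle_pair_weight <- function(a, b) {
  key <- paste0(sort(c(a, b)), collapse = "")
  switch(key, "CG" = 3L, "AU" = 2L, "GU" = 1L, 0L)
}

# true exhaustive enumeration of every nested structure (exponential; keep
# sequences short)
oracle_fold_enum <- function(seq, minloop = 3L) {
  s <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  rec <- function(i, j) {
    if (j - i + 1 < minloop + 2) return(0L)
    best <- rec(i + 1, j)                      # i unpaired
    for (k in (i + minloop + 1):j) {
      w <- oracle_pair_weight(s[i], s[k])
      if (w > 0) {
        inner <- if (i + 1 <= k - 1) rec(i + 1, k - 1) else 0L
        rest <- if (k + 1 <= j) rec(k + 1, j) else 0L
        best <- max(best, w + inner + rest)
      }
    }
    best
  }
  if (length(s) == 0) return(0)
  -rec(1, length(s))
}

# memoised R dynamic program (same model, independent implementation)
oracle_fold_dp <- function(seq, minloop = 3L) {
  s <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  n <- length(s)
  if (n == 0) return(0)
  M <- matrix(0L, n, n)
  if (n >= minloop + 2) {
    for (len in (minloop + 2):n) {
      for (i in 1:(n - len + 1)) {
        j <- i + len - 1
        best <- M[i + 1, j]                    # i unpaired
        for (k in (i + minloop + 1):j) {
          w <- oracle_pair_weight(s[i], s[k])
          if (w > 0) {
            inner <- if (i + 1 <= k - 1) M[i + 1, k - 1] else 0L
            rest <- if (k + 1 <= j) M[k + 1, j] else 0L
            best <- max(best, w + inner + rest)
          }
        }
        M[i, j] <- best
      }
    }
  }
  -M[1, n]
}

random_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}
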