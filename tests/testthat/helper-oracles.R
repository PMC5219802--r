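# Independent reference implementations used as oracles. These are
# deliberately naive (quadratic / exhaustive) and share no code with the
# package internals they check.

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# ---- brute-force chain oracle ------------------------------------------
# Maximum chain score over all valid anchor subsets by DFS extension:
# strictly increasing idx_a and idx_b (forward) or decreasing idx_b
# (reverse), per-axis gaps <= max_gap, gap cost gap_penalty*(da+db-2).
oracle_best_chain_score <- function(anchors, params) {
  n <- nrow(anchors)
  if (!n) return(-Inf)
  best <- -Inf
  for (dir in c(1, -1)) {
    ia <- anchors$idx_a
    ib <- anchors$idx_b * dir
    extend <- function(last, score) {
      best <<- max(best, score)
      for (nxt in seq_len(n)) {
        da <- ia[nxt] - ia[last]
        db <- ib[nxt] - ib[last]
        if (da >= 1 && db >= 1 && da <= params$max_gap &&
            db <= params$max_gap) {
          extend(nxt, score + anchors$score[nxt] -
                   params$gap_penalty * (da + db - 2))
        }
      }
    }
    for (start in seq_len(n)) extend(start, anchors$score[start])
  }
  best
}

# ---- quadratic-time Gotoh aligner oracle -------------------------------
# Global affine-gap alignment with traceback; gap of length L costs
# gap_open + gap_ext * L (the Biostrings convention).
oracle_global_align <- function(a, b, submat, gap_open = 11, gap_ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # match/mismatch state
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (moving along a)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a
  M[1, 1] <- 0
  for (i in seq_len(n) + 1)
    X[i, 1] <- -gap_open - gap_ext * (i - 1)
  for (j in seq_len(m) + 1)
    Y[1, j] <- -gap_open - gap_ext * (j - 1)
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- submat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(X[i - 1, j] - gap_ext,
                     M[i - 1, j] - gap_open - gap_ext,
                     Y[i - 1, j] - gap_open - gap_ext)
      Y[i, j] <- max(Y[i, j - 1] - gap_ext,
                     M[i, j - 1] - gap_open - gap_ext,
                     X[i, j - 1] - gap_open - gap_ext)
    }
  }
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  # traceback for identity / mismatch / gap summaries
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  pa <- character(0); pb <- character(0)
  while (i > 1 || j > 1) {
    if (state == 1L) {
      s <- submat[av[i - 1], bv[j - 1]]
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state_next <- which.max(prev)
      pa <- c(av[i - 1], pa); pb <- c(bv[j - 1], pb)
      i <- i - 1; j <- j - 1
      state <- state_next
    } else if (state == 2L) {
      opts <- c(X[i - 1, j] - gap_ext,
                M[i - 1, j] - gap_open - gap_ext,
                Y[i - 1, j] - gap_open - gap_ext)
      state_next <- c(2L, 1L, 3L)[which.max(opts)]
      pa <- c(av[i - 1], pa); pb <- c("-", pb)
      i <- i - 1
      state <- state_next
    } else {
      opts <- c(Y[i, j - 1] - gap_ext,
                M[i, j - 1] - gap_open - gap_ext,
                X[i, j - 1] - gap_open - gap_ext)
      state_next <- c(3L, 1L, 2L)[which.max(opts)]
      pa <- c("-", pa); pb <- c(bv[j - 1], pb)
      j <- j - 1
      state <- state_next
    }
  }
  both <- pa != "-" & pb != "-"
  runs <- function(g) sum(diff(c(FALSE, g)) == 1L)
  list(score = score,
       length = length(pa),
       pident = round(100 * sum(both & pa == pb) / length(pa), 2),
       mismatch = sum(both & pa != pb),
       gapopen = runs(pa == "-") + runs(pb == "-"))
}

# ---- exhaustive hypergeometric tail oracle -----------------------------
# P[X >= k] when drawing n from N with K successes, by enumerating all
# C(N, n) draws.
oracle_hyper_upper_tail <- function(k, K, N, n) {
  is_hit <- c(rep(TRUE, K), rep(FALSE, N - K))
  draws <- combn(N, n)
  hits <- colSums(matrix(is_hit[draws], nrow = n))
  mean(hits >= k)
}

# ---- brute-force DAG closure oracle ------------------------------------
# Transitive ancestor closure by repeated edge expansion.
oracle_closure <- function(parents) {
  anc <- parents
  repeat {
    changed <- FALSE
    for (id in names(anc)) {
      grown <- unique(c(anc[[id]], unlist(anc[anc[[id]]])))
      if (length(grown) > length(anc[[id]])) {
        anc[[id]] <- grown
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(anc, sort)
}

# ---- NG86 hand-count oracle for fourfold third-position changes --------
# For a pair differing only by fourfold-degenerate third-position
# transversions, the NG86 Ks is the JC-corrected p with S counted by the
# equal-weight site rules; computed here from first principles.
oracle_ng86_fourfold <- function(codons_a, codons_b, n_diffs) {
  gc_tab <- Biostrings::GENETIC_CODE
  sense <- names(gc_tab)[gc_tab != "*"]
  syn_fraction <- function(codon) {
    total <- 0; syn <- 0
    for (pos in 1:3) {
      for (nt in c("T", "C", "A", "G")) {
        if (substr(codon, pos, pos) == nt) next
        mut <- codon
        substr(mut, pos, pos) <- nt
        if (!mut %in% sense) next
        total <- total + 1
        if (gc_tab[[mut]] == gc_tab[[codon]]) syn <- syn + 1
      }
    }
    3 * syn / total
  }
  S <- (sum(vapply(codons_a, syn_fraction, numeric(1))) +
        sum(vapply(codons_b, syn_fraction, numeric(1)))) / 2
  p <- n_diffs / S
  -0.75 * log(1 - 4 * p / 3)
}
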