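# Pairwise Ka/Ks estimation by counting methods: protein-guided codon
# alignment, NG86 (equal-weight pathway counting + Jukes-Cantor) and a
# YN00-style estimator (kappa from fourfold-degenerate sites, F3x4
# codon-frequency weighted site counts, K80-type multiple-hit correction
# applied separately to transitions and transversions).

# Pathway-averaged difference counts for every pair of sense codons.
# For codons differing at d positions, all d! orderings of single changes
# are enumerated; orderings passing through a stop codon are discarded and
# the remaining pathways weighted equally. Each step contributes to one of
# four classes: synonymous transition/transversion, nonsynonymous
# transition/transversion. Returns four 61 x 61 matrices.
codon_diff_tables <- function() {
  cached <- .paleodup_cache$diff_tables
  if (!is.null(cached)) return(cached)
  uni <- codon_universe()
  n <- uni$n
  cmat <- do.call(rbind, strsplit(uni$codons, ""))
  idx <- setNames(seq_len(n), uni$codons)
  tabs <- list(sts = matrix(0, n, n), stv = matrix(0, n, n),
               nts = matrix(0, n, n), ntv = matrix(0, n, n))
  perms <- list(`1` = matrix(1L, 1, 1),
                `2` = rbind(c(1L, 2L), c(2L, 1L)),
                `3` = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                            c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      dpos <- which(cmat[i, ] != cmat[j, ])
      d <- length(dpos)
      if (d == 0L) next
      ord <- perms[[as.character(d)]]
      acc <- c(sts = 0, stv = 0, nts = 0, ntv = 0)
      nvalid <- 0L
      for (p in seq_len(nrow(ord))) {
        cur <- cmat[i, ]
        steps <- c(sts = 0, stv = 0, nts = 0, ntv = 0)
        ok <- TRUE
        for (pos in dpos[ord[p, seq_len(d)]]) {
          nxt <- cur
          nxt[pos] <- cmat[j, pos]
          to <- idx[paste(nxt, collapse = "")]
          if (is.na(to)) { ok <- FALSE; break }
          from <- idx[paste(cur, collapse = "")]
          syn <- uni$aa[from] == uni$aa[to]
          ts <- is_transition(cur[pos], nxt[pos])
          cls <- paste0(if (syn) "s" else "n", if (ts) "ts" else "tv")
          steps[cls] <- steps[cls] + 1
          cur <- nxt
        }
        if (ok) { acc <- acc + steps; nvalid <- nvalid + 1L }
      }
      if (nvalid == 0L) {
        # all orderings pass through a stop (rare); fall back to direct
        # per-position classification against codon i's context
        for (pos in dpos) {
          nxt <- cmat[i, ]
          nxt[pos] <- cmat[j, pos]
          to <- idx[paste(nxt, collapse = "")]
          syn <- !is.na(to) && uni$aa[i] == uni$aa[to]
          ts <- is_transition(cmat[i, pos], cmat[j, pos])
          cls <- paste0(if (syn) "s" else "n", if (ts) "ts" else "tv")
          acc[cls] <- acc[cls] + 1
        }
        nvalid <- 1L
      }
      acc <- acc / nvalid
      for (cls in names(tabs)) {
        tabs[[cls]][i, j] <- acc[cls]
        tabs[[cls]][j, i] <- acc[cls]
      }
    }
  }
  .paleodup_cache$diff_tables <- tabs
  tabs
}

# Codons whose third position is fourfold degenerate (any third-position
# change is sense and synonymous).
fourfold_codons <- function() {
  cached <- .paleodup_cache$fourfold
  if (!is.null(cached)) return(cached)
  uni <- codon_universe()
  pre <- substr(uni$codons, 1, 2)
  ff <- vapply(seq_along(uni$codons), function(i) {
    fam <- which(pre == pre[i])
    length(fam) == 4L && length(unique(uni$aa[fam])) == 1L
  }, logical(1))
  .paleodup_cache$fourfold <- ff
  ff
}

# F3x4 codon frequencies from the codons of both sequences.
f3x4_frequencies <- function(codons_a, codons_b) {
  uni <- codon_universe()
  cmat <- do.call(rbind, strsplit(uni$codons, ""))
  all_cod <- c(codons_a, codons_b)
  pi <- rep(1, uni$n)
  for (pos in 1:3) {
    f <- table(factor(cmat[all_cod, pos], levels = NUCS)) + 0.5  # small prior
    f <- as.numeric(f / sum(f))
    pi <- pi * f[match(cmat[, pos], NUCS)]
  }
  pi / sum(pi)
}

# Kimura two-parameter distance decomposed into transition and transversion
# components, with the delta-method variance of the total distance.
# P = proportion of transition differences, Q = transversions, n = sites.
k80_distance <- function(P, Q, n) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    return(list(d = NA_real_, a = NA_real_, b = NA_real_, se = NA_real_,
                saturated = TRUE))
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  a <- -0.5 * log(w1) + 0.25 * log(w2)
  b <- -0.5 * log(w2)
  c1 <- 1 / w1
  c2 <- 0.5 * (1 / w1 + 1 / w2)
  v <- (c1^2 * P + c2^2 * Q - (c1 * P + c2 * Q)^2) / n
  list(d = d, a = a, b = b, se = sqrt(max(v, 0)), saturated = FALSE)
}

# kappa (ts/tv rate ratio) from fourfold-degenerate third positions using
# the K80 decomposition; NA when inestimable.
estimate_kappa_fourfold <- function(codons_a, codons_b) {
  uni <- codon_universe()
  ff <- fourfold_codons()
  pre_a <- substr(uni$codons[codons_a], 1, 2)
  pre_b <- substr(uni$codons[codons_b], 1, 2)
  use <- ff[codons_a] & ff[codons_b] & pre_a == pre_b
  n4 <- sum(use)
  if (n4 < 10L) return(NA_real_)
  nt_a <- substr(uni$codons[codons_a[use]], 3, 3)
  nt_b <- substr(uni$codons[codons_b[use]], 3, 3)
  diff <- nt_a != nt_b
  ts <- diff & mapply(is_transition, nt_a, nt_b)
  P <- sum(ts) / n4
  Q <- sum(diff & !ts) / n4
  k <- k80_distance(P, Q, n4)
  if (k$saturated || !is.finite(k$b) || k$b <= 0) return(NA_real_)
  min(max(2 * k$a / k$b, 0.2), 20)
}

#' Protein-guided pairwise codon alignment
#'
#' Globally aligns the translated proteins of two coding sequences
#' (BLOSUM62, affine gaps) and back-translates the alignment onto codons.
#' Columns with a gap in either row, and codons containing ambiguity
#' characters, are removed before counting.
#'
#' @param cds_a,cds_b coding sequences (character or `DNAString`), lengths
#'   divisible by 3; internal stop codons are an error. A terminal stop is
#'   tolerated and trimmed.
#' @param ids optional character vector of length 2 naming the sequences in
#'   error messages.
#' @param guide `"protein"` (default) aligns via the translated proteins;
#'   `"none"` requires equal-length sequences and pairs codons positionally
#'   (useful for simulated, indel-free pairs).
#' @param gap_opening,gap_extension affine gap penalties for the protein
#'   alignment.
#' @return An object of class `codon_alignment`: list with `codons_a`,
#'   `codons_b` (sense-codon index vectors of retained columns),
#'   `n_codons_used`, `n_ambiguous_dropped` and `ids`.
#' @export
codon_align <- function(cds_a, cds_b, ids = c("seq_a", "seq_b"),
                        guide = c("protein", "none"),
                        gap_opening = 11, gap_extension = 1) {
  guide <- match.arg(guide)
  trip_a <- split_triplets(cds_a, ids[1])
  trip_b <- split_triplets(cds_b, ids[2])
  if (guide == "none") {
    if (length(trip_a) != length(trip_b))
      stop("guide = 'none' requires equal-length sequences")
    cols <- cbind(seq_along(trip_a), seq_along(trip_b))
  } else {
    aa_a <- translate_triplets(trip_a, ids[1])
    aa_b <- translate_triplets(trip_b, ids[2])
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(paste(aa_a, collapse = "")),
      Biostrings::AAString(paste(aa_b, collapse = "")),
      substitutionMatrix = blosum62(), type = "global",
      gapOpening = gap_opening, gapExtension = gap_extension)
    pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ia <- cumsum(pat != "-")
    ib <- cumsum(sub != "-")
    keep <- pat != "-" & sub != "-"
    cols <- cbind(ia[keep], ib[keep])
  }
  uni <- codon_universe()
  ca <- match(trip_a[cols[, 1]], uni$codons)
  cb <- match(trip_b[cols[, 2]], uni$codons)
  ok <- !is.na(ca) & !is.na(cb)  # drops ambiguity-containing codons
  structure(list(codons_a = ca[ok], codons_b = cb[ok],
                 n_codons_used = sum(ok),
                 n_ambiguous_dropped = sum(!ok), ids = ids),
            class = "codon_alignment")
}

# split a CDS into codon triplets, trimming a terminal stop and rejecting
# internal stops with the sequence id and codon index
split_triplets <- function(cds, id) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("sequence ", id, ": length ", n, " not divisible by 3")
  trip <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  stops <- which(trip %in% c("TAA", "TAG", "TGA"))
  if (length(stops)) {
    if (any(stops < length(trip)))
      stop("sequence ", id, ": internal stop codon at codon ",
           stops[stops < length(trip)][1])
    trip <- trip[-length(trip)]
  }
  trip
}

translate_triplets <- function(trip, id) {
  uni <- codon_universe()
  aa <- uni$aa[match(trip, uni$codons)]
  aa[is.na(aa)] <- "X"
  aa
}

blosum62 <- function() {
  if (is.null(.paleodup_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .paleodup_cache$blosum62 <- e$BLOSUM62
  }
  .paleodup_cache$blosum62
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon alignment:", x$ids[1], "vs", x$ids[2], "-",
      x$n_codons_used, "codon columns retained",
      if (x$n_ambiguous_dropped) paste0("(", x$n_ambiguous_dropped,
                                        " ambiguous dropped)") else "", "\n")
  invisible(x)
}

#' Estimate Ka and Ks for an aligned codon pair
#'
#' Counting-based estimation of synonymous (Ks) and nonsynonymous (Ka)
#' substitutions per site. `method = "YN00"` estimates the
#' transition/transversion rate ratio kappa from fourfold-degenerate sites,
#' counts sites with F3x4 codon-frequency and kappa weighting
#' (mutational-opportunity counting, stops excluded) and counts differences
#' by equal-weight pathway averaging split into transitions and
#' transversions. Two multiple-hit corrections are available:
#'
#' * `correction = "model"` (default): the observed per-codon synonymous and
#'   nonsynonymous difference counts are matched against their expectation
#'   under an HKY-type codon substitution model built from the estimated
#'   kappa, omega and F3x4 frequencies, solving for the divergence time;
#'   omega (and kappa, when fourfold-degenerate sites are saturated) is
#'   iterated to convergence. This correction stays consistent up to the
#'   Ks ~ 2 working range, where closed-form corrections that pool
#'   heterogeneous synonymous site classes into a single Kimura site
#'   overshoot substantially.
#' * `correction = "k80"`: the classic closed form, Kimura two-parameter
#'   correction applied to the pooled synonymous (and nonsynonymous)
#'   transition/transversion proportions.
#'
#' `method = "NG86"` uses equal-weight site and pathway counting with a
#' Jukes-Cantor correction. The standard error of Ks is in all cases the
#' delta-method SE of the corrected synonymous proportion.
#'
#' @param alignment a `codon_alignment` (or list with `codons_a`,
#'   `codons_b` sense-codon index vectors).
#' @param method `"YN00"` (default) or `"NG86"`.
#' @param correction multiple-hit correction for `"YN00"`: `"model"`
#'   (default) or `"k80"`.
#' @param min_codons minimum retained codon columns (default 30).
#' @return A one-row data.frame: `ks`, `ka`, `se` (SE of Ks), `kappa_hat`,
#'   `omega_hat`, `n_codons`, `method`, `saturated`.
#' @export
estimate_ks <- function(alignment, method = c("YN00", "NG86"),
                        correction = c("model", "k80"), min_codons = 30L) {
  method <- match.arg(method)
  correction <- match.arg(correction)
  ca <- alignment$codons_a
  cb <- alignment$codons_b
  L <- length(ca)
  if (L < min_codons)
    stop("only ", L, " aligned codon columns; need >= ", min_codons)
  tabs <- codon_diff_tables()
  pair_idx <- cbind(ca, cb)
  sts <- sum(tabs$sts[pair_idx]); stv <- sum(tabs$stv[pair_idx])
  nts <- sum(tabs$nts[pair_idx]); ntv <- sum(tabs$ntv[pair_idx])

  if (method == "NG86") {
    s_cod <- syn_sites_per_codon(kappa = 1, pi = NULL)
    S <- (sum(s_cod[ca]) + sum(s_cod[cb])) / 2
    N <- 3 * L - S
    jc <- function(p, n) {
      if (p >= 0.75) return(list(d = NA_real_, se = NA_real_, saturated = TRUE))
      d <- -0.75 * log(1 - 4 * p / 3)
      v <- 9 * p * (1 - p) / ((3 - 4 * p)^2 * n)
      list(d = d, se = sqrt(max(v, 0)), saturated = FALSE)
    }
    ks_fit <- jc((sts + stv) / S, S)
    ka_fit <- jc((nts + ntv) / N, N)
    return(data.frame(ks = ks_fit$d, ka = ka_fit$d, se = ks_fit$se,
                      kappa_hat = NA_real_, omega_hat = NA_real_,
                      n_codons = L, method = method,
                      saturated = ks_fit$saturated, stringsAsFactors = FALSE))
  }

  kappa_hat <- estimate_kappa_fourfold(ca, cb)
  pi <- f3x4_frequencies(ca, cb)

  if (correction == "k80") {
    kappa_use <- if (is.na(kappa_hat)) 1 else kappa_hat
    s_cod <- syn_sites_per_codon(kappa_use, pi)
    S <- (sum(s_cod[ca]) + sum(s_cod[cb])) / 2
    N <- 3 * L - S
    ks_fit <- k80_distance(sts / S, stv / S, S)
    ka_fit <- k80_distance(nts / N, ntv / N, N)
    return(data.frame(ks = ks_fit$d, ka = ka_fit$d, se = ks_fit$se,
                      kappa_hat = kappa_hat, omega_hat = NA_real_,
                      n_codons = L, method = method,
                      saturated = ks_fit$saturated, stringsAsFactors = FALSE))
  }

  yn00_model_inversion(ca, cb, sts, stv, nts, ntv, kappa_hat, pi, L, method)
}

# Model-expectation inversion for the YN00 estimator: solve for the
# divergence time at which the expected per-codon synonymous difference
# count under the fitted codon model equals the observed count, iterating
# omega (and kappa when fourfold-degenerate sites were saturated).
yn00_model_inversion <- function(ca, cb, sts, stv, nts, ntv,
                                 kappa_hat, pi, L, method) {
  tabs <- codon_diff_tables()
  syn_tab <- tabs$sts + tabs$stv
  non_tab <- tabs$nts + tabs$ntv
  out <- function(ks, ka, se, kappa, omega, saturated) {
    data.frame(ks = ks, ka = ka, se = se, kappa_hat = kappa,
               omega_hat = omega, n_codons = L, method = method,
               saturated = saturated, stringsAsFactors = FALSE)
  }
  sd_obs <- (sts + stv) / L  # syn differences per codon
  nd_obs <- (nts + ntv) / L
  if (sd_obs == 0 && nd_obs == 0)
    return(out(0, 0, 0, kappa_hat, NA_real_, FALSE))

  iterate_kappa <- is.na(kappa_hat)
  kappa <- if (iterate_kappa) 2 else kappa_hat
  omega <- 0.5
  t_max <- 30
  t_hat <- NA_real_
  for (iter in 1:12) {
    model <- codon_rate_matrix(kappa, omega, pi)
    eig <- codon_model_eigen(model)
    e_syn <- function(t) {
      J <- model$pi * transition_from_eigen(eig, t)
      sum(J * syn_tab)
    }
    if (sd_obs >= e_syn(t_max) * 0.999)
      return(out(NA_real_, NA_real_, NA_real_, kappa, omega, TRUE))
    t_hat <- if (sd_obs == 0) 0 else
      uniroot(function(t) e_syn(t) - sd_obs, c(1e-9, t_max), tol = 1e-9)$root
    J <- model$pi * transition_from_eigen(eig, t_hat)
    converged <- TRUE
    if (t_hat > 0) {
      en <- sum(J * non_tab)
      if (en > 0 && nd_obs > 0) {
        omega_new <- min(max(omega * nd_obs / en * sum(J * syn_tab) / sd_obs, 0.005), 10)
        if (abs(log(omega_new / omega)) > 1e-3) converged <- FALSE
        omega <- omega_new
      }
      if (iterate_kappa) {
        ets <- sum(J * tabs$sts); etv <- sum(J * tabs$stv)
        if (ets > 0 && etv > 0 && sts > 0 && stv > 0) {
          kappa_new <- min(max(kappa * (sts / stv) / (ets / etv), 0.2), 20)
          if (abs(log(kappa_new / kappa)) > 1e-3) converged <- FALSE
          kappa <- kappa_new
        }
      }
    }
    if (converged && iter > 1) break
  }
  model <- codon_rate_matrix(kappa, omega, pi)
  eig <- codon_model_eigen(model)
  s_cod <- syn_sites_per_codon(kappa, pi)
  s_per_codon <- (sum(s_cod[ca]) + sum(s_cod[cb])) / 2 / L
  n_per_codon <- 3 - s_per_codon
  uni <- codon_universe()
  nb <- uni$neighbors
  syn_nb <- nb[nb$syn, ]; non_nb <- nb[!nb$syn, ]
  flux_s <- sum(model$pi[syn_nb$i] * model$Q[cbind(syn_nb$i, syn_nb$j)])
  flux_n <- sum(model$pi[non_nb$i] * model$Q[cbind(non_nb$i, non_nb$j)])
  ks <- t_hat * flux_s / s_per_codon
  ka <- t_hat * flux_n / n_per_codon
  # delta-method SE of Ks from the observed synonymous proportion
  S_tot <- s_per_codon * L
  ps <- (sts + stv) / S_tot
  dt <- max(t_hat, 0.05) * 1e-3
  e_syn2 <- function(t) sum((model$pi * transition_from_eigen(eig, t)) * syn_tab)
  dps_dt <- (e_syn2(t_hat + dt) - e_syn2(max(t_hat - dt, 0))) /
    (dt + min(dt, t_hat)) / s_per_codon
  dks_dt <- flux_s / s_per_codon
  se <- if (dps_dt > 0)
    sqrt(max(ps * (1 - ps) / S_tot, 0)) * dks_dt / dps_dt else NA_real_
  out(ks, ka, se, kappa, if (t_hat > 0) omega else NA_real_, FALSE)
}

#' Ks estimates for a table of gene pairs
#'
#' Convenience wrapper: aligns each pair with [codon_align()] and estimates
#' divergence with [estimate_ks()].
#'
#' @param cds named character vector (or `DNAStringSet`) of coding
#'   sequences.
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @inheritParams estimate_ks
#' @return data.frame with one row per pair: `gene_a`, `gene_b`, `ks`,
#'   `ka`, `se`, `kappa_hat`, `n_codons`, `saturated`. Pairs with fewer than
#'   `min_codons` aligned columns get NA estimates and `saturated = TRUE`.
#' @export
ks_for_pairs <- function(cds, pairs, method = "YN00", min_codons = 30L) {
  cds <- setNames(as.character(cds), names(cds))
  if (is.null(names(cds))) stop("cds must be named by gene id")
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    est <- tryCatch({
      aln <- codon_align(cds[[a]], cds[[b]], ids = c(a, b))
      estimate_ks(aln, method = method, min_codons = min_codons)
    }, error = function(e) {
      data.frame(ks = NA_real_, ka = NA_real_, se = NA_real_,
                 kappa_hat = NA_real_, n_codons = 0L, method = method,
                 saturated = TRUE, stringsAsFactors = FALSE)
    })
    res[[i]] <- cbind(data.frame(gene_a = a, gene_b = b,
                                 stringsAsFactors = FALSE), est)
  }
  do.call(rbind, res)
}

#' Apply the Ks and standard-error retention filters
#'
#' Keeps estimates with `ks <= max_ks` (inclusive) and `se < max_se`
#' (strict), dropping saturated or failed estimates. Exclusion counts by
#' reason are attached as attribute `"excluded"` and reported via
#' `message()`.
#'
#' @param estimates data.frame from [ks_for_pairs()] (needs `ks`, `se`,
#'   `saturated`).
#' @param max_ks maximum Ks retained (default 2, inclusive).
#' @param max_se maximum standard error (default 0.5, exclusive).
#' @param quiet suppress the attrition message.
#' @return the filtered data.frame.
#' @export
filter_estimates <- function(estimates, max_ks = 2, max_se = 0.5,
                             quiet = FALSE) {
  bad_est <- estimates$saturated | is.na(estimates$ks) | is.na(estimates$se)
  high_ks <- !bad_est & estimates$ks > max_ks
  high_se <- !bad_est & !high_ks & estimates$se >= max_se
  keep <- !(bad_est | high_ks | high_se)
  excluded <- c(saturated_or_failed = sum(bad_est),
                ks_above_max = sum(high_ks),
                se_above_max = sum(high_se))
  if (!quiet && sum(!keep) > 0)
    message("filter_estimates: removed ", sum(!keep), " pairs (",
            paste(names(excluded), excluded, sep = "=", collapse = ", "), ")")
  out <- estimates[keep, , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}
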