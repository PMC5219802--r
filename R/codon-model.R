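# Codon-level machinery shared by the simulator and the Ks estimators:
# the sense-codon universe, single-nucleotide neighbourhoods, a GY-style
# rate matrix, and mutational-opportunity site counting.

PURINES <- c("A", "G")
NUCS <- c("T", "C", "A", "G")

#' Sense-codon universe for the standard genetic code
#'
#' Returns (and caches) the 61 sense codons of the standard genetic code
#' together with their amino-acid translations and the table of all
#' single-nucleotide changes between sense codons. Changes that create a
#' stop codon are excluded throughout: the simulator's substitution process
#' rejects them and the site-counting rules ignore them.
#'
#' @return A list with elements `codons` (character, length 61), `aa`
#'   (character, length 61), `n` (61) and `neighbors`, a data.frame with one
#'   row per ordered single-nucleotide change i -> j between sense codons and
#'   columns `i`, `j` (codon indices), `pos` (1-3), `ts` (logical, transition)
#'   and `syn` (logical, synonymous).
#' @export
codon_universe <- function() {
  cached <- .paleodup_cache$universe
  if (!is.null(cached)) return(cached)
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)[gc_tab != "*"]
  aa <- unname(gc_tab[codons])
  n <- length(codons)
  idx <- setNames(seq_len(n), codons)
  cmat <- do.call(rbind, strsplit(codons, ""))
  rows <- vector("list", n * 9L)
  k <- 0L
  for (i in seq_len(n)) {
    for (pos in 1:3) {
      for (nt in NUCS) {
        if (nt == cmat[i, pos]) next
        mutated <- cmat[i, ]
        mutated[pos] <- nt
        target <- paste(mutated, collapse = "")
        j <- idx[target]
        if (is.na(j)) next  # stop codon
        k <- k + 1L
        rows[[k]] <- c(i, j, pos,
                       as.integer(is_transition(cmat[i, pos], nt)),
                       as.integer(aa[i] == aa[j]))
      }
    }
  }
  nb <- as.data.frame(do.call(rbind, rows[seq_len(k)]))
  names(nb) <- c("i", "j", "pos", "ts", "syn")
  nb$ts <- as.logical(nb$ts)
  nb$syn <- as.logical(nb$syn)
  out <- list(codons = codons, aa = aa, n = n, neighbors = nb)
  .paleodup_cache$universe <- out
  out
}

is_transition <- function(from, to) {
  (from %in% PURINES) == (to %in% PURINES)
}

#' Convert CDS character strings to codon index vectors and back
#'
#' @param cds a single DNA string (character or `DNAString`), length
#'   divisible by 3, containing no internal stop codon.
#' @return `cds_to_codons`: integer vector of indices into
#'   `codon_universe()$codons`; `codons_to_cds`: a character string.
#' @export
cds_to_codons <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length ", nchar(cds), " is not divisible by 3")
  uni <- codon_universe()
  trip <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  out <- match(trip, uni$codons)
  bad <- which(is.na(out))
  if (length(bad)) {
    trip_bad <- trip[bad[1L]]
    if (trip_bad %in% c("TAA", "TAG", "TGA") && bad[1L] < length(trip))
      stop("internal stop codon ", trip_bad, " at codon ", bad[1L])
    if (trip_bad %in% c("TAA", "TAG", "TGA")) {
      out <- out[-length(out)]  # tolerate a terminal stop
    } else {
      stop("unrecognised codon '", trip_bad, "' at codon ", bad[1L])
    }
  }
  out
}

#' @rdname cds_to_codons
#' @param codons integer vector of sense-codon indices.
#' @export
codons_to_cds <- function(codons) {
  paste(codon_universe()$codons[codons], collapse = "")
}

#' GY-style codon substitution rate matrix
#'
#' Builds the 61 x 61 instantaneous rate matrix of a Goldman-Yang-type codon
#' model: single-nucleotide changes only, rate proportional to the target
#' codon frequency, multiplied by `kappa` for transitions and by `omega` for
#' nonsynonymous changes. Changes to stop codons have rate zero.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (> 0).
#' @param pi codon equilibrium frequencies (length 61, summing to 1);
#'   default uniform.
#' @return list with `Q` (rate matrix, rows summing to zero) and `pi`.
#' @export
codon_rate_matrix <- function(kappa = 2, omega = 0.2, pi = NULL) {
  stopifnot(kappa > 0, omega > 0)
  uni <- codon_universe()
  if (is.null(pi)) pi <- rep(1 / uni$n, uni$n)
  stopifnot(length(pi) == uni$n, all(pi > 0))
  pi <- pi / sum(pi)
  nb <- uni$neighbors
  rate <- pi[nb$j] * ifelse(nb$ts, kappa, 1) * ifelse(nb$syn, 1, omega)
  Q <- matrix(0, uni$n, uni$n, dimnames = list(uni$codons, uni$codons))
  Q[cbind(nb$i, nb$j)] <- rate
  diag(Q) <- -rowSums(Q)
  list(Q = Q, pi = pi)
}

#' Mutational-opportunity synonymous site counts per codon
#'
#' For each sense codon, the number of synonymous sites out of 3, counted as
#' the kappa- and frequency-weighted fraction of single-nucleotide mutation
#' opportunity that is synonymous; changes to stop codons are excluded from
#' both numerator and denominator. With `kappa = 1` and uniform `pi` this
#' reduces to the classic NG86 site fractions (with stops excluded).
#'
#' @inheritParams codon_rate_matrix
#' @return numeric vector of length 61 (synonymous sites per codon).
#' @export
syn_sites_per_codon <- function(kappa = 1, pi = NULL) {
  uni <- codon_universe()
  if (is.null(pi)) pi <- rep(1 / uni$n, uni$n)
  nb <- uni$neighbors
  w <- pi[nb$j] * ifelse(nb$ts, kappa, 1)
  wsyn <- tapply(w * nb$syn, nb$i, sum)
  wtot <- tapply(w, nb$i, sum)
  s <- rep(0, uni$n)
  s[as.integer(names(wtot))] <- 3 * as.numeric(wsyn) / as.numeric(wtot)
  s
}

# Expected synonymous substitutions per codon per unit time under Q at
# codon-composition f (defaults to the stationary distribution).
syn_flux <- function(model, f = NULL) {
  uni <- codon_universe()
  if (is.null(f)) f <- model$pi
  nb <- uni$neighbors
  syn_nb <- nb[nb$syn, ]
  sum(f[syn_nb$i] * model$Q[cbind(syn_nb$i, syn_nb$j)])
}

# Eigensystem of a reversible Q, symmetrised with sqrt(pi), so that
# repeated P(t) evaluations are cheap.
codon_model_eigen <- function(model) {
  d <- sqrt(model$pi)
  B <- (d * model$Q) %*% diag(1 / d)  # diag(d) %*% Q %*% diag(1/d)
  B <- (B + t(B)) / 2                 # symmetric up to rounding
  eig <- eigen(B, symmetric = TRUE)
  list(values = eig$values, vectors = eig$vectors, d = d)
}

# Transition-probability matrix P(t) = expm(Q t) from a cached eigensystem.
transition_from_eigen <- function(eig, t) {
  if (t <= 0) return(diag(length(eig$d)))
  P <- (eig$vectors * rep(exp(eig$values * t), each = length(eig$d))) %*%
    t(eig$vectors)
  P <- P * rep(eig$d, each = length(eig$d)) / eig$d  # diag(1/d) P diag(d)
  P[P < 0] <- 0
  P / rowSums(P)
}

# Transition-probability matrix P(t) = expm(Q t) for a reversible Q.
codon_transition_matrix <- function(model, t) {
  transition_from_eigen(codon_model_eigen(model), t)
}

# Memoised model + eigensystem + Ks-per-unit-time calibration for the
# simulator (time units: expected syn substitutions per syn site = 1).
cached_codon_model <- function(kappa, omega) {
  key <- paste0("model_", kappa, "_", omega)
  cached <- .paleodup_cache[[key]]
  if (!is.null(cached)) return(cached)
  model <- codon_rate_matrix(kappa, omega)
  out <- list(model = model,
              eig = codon_model_eigen(model),
              ks_per_time = syn_flux(model) /
                mean(syn_sites_per_codon(kappa, model$pi)))
  .paleodup_cache[[key]] <- out
  out
}

# Draw descendant codons for each ancestor codon from P(t); vectorised by
# ancestor state.
sample_descendants <- function(codons, P) {
  out <- integer(length(codons))
  for (state in unique(codons)) {
    at <- which(codons == state)
    out[at] <- sample.int(ncol(P), length(at), replace = TRUE, prob = P[state, ])
  }
  out
}

#' Evolve a codon sequence into a diverged descendant pair
#'
#' Simulates codon substitutions along two independent branches from a
#' common ancestor under a GY-style codon model. Branch lengths are
#' calibrated so that the summed expected synonymous divergence of the pair,
#' measured in synonymous substitutions per (kappa-weighted,
#' mutational-opportunity) synonymous site, equals `target_ks`. Stop codons
#' are unreachable by construction, so descendants always translate cleanly.
#'
#' @param ancestor_cds ancestor coding sequence (character/`DNAString`,
#'   length divisible by 3, no internal stop) or an integer codon-index
#'   vector.
#' @param target_ks target pairwise synonymous divergence (>= 0).
#' @param kappa transition/transversion rate ratio.
#' @param omega dN/dS ratio.
#' @param split fraction of the divergence assigned to the first branch
#'   (default 0.5).
#' @return list with `cds_a`, `cds_b` (character CDS strings), the realised
#'   branch calibration `ks_a`, `ks_b`, and `codons_a`, `codons_b`
#'   (index vectors).
#' @examples
#' anc <- strrep("ATGGCT", 60)
#' pair <- evolve_codon_pair(anc, target_ks = 0.3)
#' @export
evolve_codon_pair <- function(ancestor_cds, target_ks, kappa = 2,
                              omega = 0.2, split = 0.5) {
  stopifnot(target_ks >= 0, split >= 0, split <= 1)
  codons <- if (is.numeric(ancestor_cds)) as.integer(ancestor_cds)
            else cds_to_codons(ancestor_cds)
  if (target_ks == 0) {
    cds <- codons_to_cds(codons)
    return(list(cds_a = cds, cds_b = cds, ks_a = 0, ks_b = 0,
                codons_a = codons, codons_b = codons))
  }
  cm <- cached_codon_model(kappa, omega)
  ks_a <- target_ks * split
  ks_b <- target_ks * (1 - split)
  cod_a <- sample_descendants(codons, transition_from_eigen(cm$eig, ks_a / cm$ks_per_time))
  cod_b <- sample_descendants(codons, transition_from_eigen(cm$eig, ks_b / cm$ks_per_time))
  list(cds_a = codons_to_cds(cod_a), cds_b = codons_to_cds(cod_b),
       ks_a = ks_a, ks_b = ks_b, codons_a = cod_a, codons_b = cod_b)
}
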