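# Shared fixtures, generated in code. The default cohort at seed 1 is
# cached per test run because several files probe different stages of it.

.cohortCache <- new.env(parent = emptyenv())

defaultCohort <- function(seed = 1) {
  key <- paste0("seed", seed)
  if (is.null(.cohortCache[[key]]))
    .cohortCache[[key]] <- generateCohort(cohortConfig(seed = seed))
  .cohortCache[[key]]
}

nullConfig <- function(seed = 1) {
  cohortConfig(n_planted_dss = 0L, n_planted_de = 0L,
               n_planted_de_lnc = 0L, n_planted_cerna = 0L,
               n_planted_cis = 0L, n_trans_targets = 0L,
               n_tf_extra_targets = 0L, n_planted_hypermeth = 0L,
               seed = seed)
}

# Small two-class expression OmicsMatrix built from a plain matrix.
omFrom <- function(values, nTumor = NULL, role = "expression") {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (is.null(nTumor)) nTumor <- ncol(values)
  cls <- rep(c("tumor", "normal"),
             c(nTumor, ncol(values) - nTumor))
  OmicsMatrix(values, cls, role)
}

# Independent step-up BH oracle (direct evaluation of the formula).
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p, seq_len(m))
  qs <- p[o] * m / seq_len(m)
  qs <- pmin(rev(cummin(rev(qs))), 1)
  q <- numeric(m)
  q[o] <- qs
  q
}

# Brute-force upper-tail hypergeometric by enumerating every M-subset of
# an N universe whose first L elements are "white".
enumTailP <- function(k, N, M, L) {
  if (k <= 0) return(1)
  if (M == 0) return(0)
  draws <- utils::combn(N, M)
  mean(colSums(draws <= L) >= k)
}
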