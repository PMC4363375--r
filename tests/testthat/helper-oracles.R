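# Independent oracles, written without reference to the package internals.

# Vectorised gene drop over R replicates returning an R x n matrix of
# allele counts (columns in pedigree id order). Independent of the
# package's drop engine: written directly from Mendelian transmission.
oracleDropMany <- function(ped, R, q = NULL, carriers = NULL) {
  d <- individuals(ped)
  ids <- d$id
  # ancestor-first ordering by repeated sweeps
  depth <- rep(NA_integer_, nrow(d))
  depth[is.na(d$father)] <- 0L
  while (anyNA(depth)) {
    for (i in which(is.na(depth))) {
      df <- depth[match(d$father[i], ids)]
      dm <- depth[match(d$mother[i], ids)]
      if (!is.na(df) && !is.na(dm)) depth[i] <- max(df, dm) + 1L
    }
  }
  ord <- order(depth)
  fi <- match(d$father[ord], ids[ord]); mi <- match(d$mother[ord], ids[ord])
  n <- length(ids)
  a1 <- matrix(0L, R, n); a2 <- matrix(0L, R, n)
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      if (!is.null(carriers)) {
        if (ids[ord][i] %in% carriers) a1[, i] <- 1L
      } else {
        a1[, i] <- stats::rbinom(R, 1L, q)
        a2[, i] <- stats::rbinom(R, 1L, q)
      }
    } else {
      pf <- stats::rbinom(R, 1L, 0.5) == 1L
      pm <- stats::rbinom(R, 1L, 0.5) == 1L
      a1[, i] <- ifelse(pf, a1[, fi[i]], a2[, fi[i]])
      a2[, i] <- ifelse(pm, a1[, mi[i]], a2[, mi[i]])
    }
  }
  G <- a1 + a2
  colnames(G) <- ids[ord]
  G[, ids, drop = FALSE]
}

# Monte-Carlo IBD estimate of kinship for chosen id pairs: drop uniquely
# labelled founder alleles and average allele-identity over the four
# ordered allele pairs. Returns estimates and their standard errors.
oracleKinshipMC <- function(ped, pairs, R = 20000) {
  d <- individuals(ped)
  ids <- d$id
  depth <- rep(NA_integer_, nrow(d))
  depth[is.na(d$father)] <- 0L
  while (anyNA(depth)) {
    for (i in which(is.na(depth))) {
      df <- depth[match(d$father[i], ids)]
      dm <- depth[match(d$mother[i], ids)]
      if (!is.na(df) && !is.na(dm)) depth[i] <- max(df, dm) + 1L
    }
  }
  ord <- order(depth)
  oid <- ids[ord]
  fi <- match(d$father[ord], oid); mi <- match(d$mother[ord], oid)
  n <- length(ids)
  L1 <- matrix(0L, R, n); L2 <- matrix(0L, R, n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      L1[, i] <- lab + 1L; L2[, i] <- lab + 2L; lab <- lab + 2L
    } else {
      pf <- stats::rbinom(R, 1L, 0.5) == 1L
      pm <- stats::rbinom(R, 1L, 0.5) == 1L
      L1[, i] <- ifelse(pf, L1[, fi[i]], L2[, fi[i]])
      L2[, i] <- ifelse(pm, L1[, mi[i]], L2[, mi[i]])
    }
  }
  t(apply(pairs, 1, function(pr) {
    i <- match(pr[1], oid); j <- match(pr[2], oid)
    ibd <- (L1[, i] == L1[, j]) + (L1[, i] == L2[, j]) +
           (L2[, i] == L1[, j]) + (L2[, i] == L2[, j])
    x <- ibd / 4
    c(est = mean(x), se = stats::sd(x) / sqrt(R))
  }))
}
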