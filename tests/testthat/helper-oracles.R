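# Independent oracles and fixture builders used across the suite.

# Brute-force DEC likelihood and marginals: explicit enumeration over every
# assignment of pre-split ranges to internal nodes and, within each
# assignment, the sum over cladogenetic outcomes per node. Branch transition
# probabilities come straight from Matrix::expm (never from the package's
# internal propagator), so this shares no code path with the pruning
# algorithm.
dec_brute <- function(tree, tips, d, e, space) {
  Q <- dec_q_matrix(space, d, e)
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  ch <- matrix(0L, nn, 2)
  cnt <- integer(nn)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    cnt[p] <- cnt[p] + 1L
    ch[p, cnt[p]] <- tree$edge[i, 2]
  }
  P <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    P[[tree$edge[i, 2]]] <- as.matrix(Matrix::expm(Q * tree$edge.length[i]))
  }
  bits <- range_bits(tips$range[match(tree$tip.label, tips$species)],
                     space$areas)
  tipidx <- match(bits, space$bits)
  S <- length(space$bits)
  nonnull <- which(space$bits != 0L)
  internal <- (nt + 1):nn
  prior <- 1 / length(nonnull)
  outcome_rows <- function(b) {
    occ <- which(bitwAnd(b, bitwShiftL(1L, seq_along(space$areas) - 1L)) > 0L)
    if (length(occ) == 1L) {
      pairs <- data.frame(l = b, r = b)
    } else {
      L <- integer(0); R <- integer(0)
      for (j in occ) {
        aj <- bitwShiftL(1L, j - 1L)
        rem <- bitwAnd(b, bitwNot(aj))
        L <- c(L, aj, rem, aj, b); R <- c(R, rem, aj, b, aj)
      }
      keep <- !duplicated(paste(L, R))
      pairs <- data.frame(l = L[keep], r = R[keep])
    }
    li <- match(pairs$l, space$bits); ri <- match(pairs$r, space$bits)
    k <- !is.na(li) & !is.na(ri)
    data.frame(l = li[k], r = ri[k], w = 1 / sum(k))
  }
  ot <- lapply(seq_len(S), function(i) {
    if (space$bits[i] == 0L) NULL else outcome_rows(space$bits[i])
  })
  grid <- do.call(expand.grid, rep(list(nonnull), length(internal)))
  L_tot <- 0
  marg <- matrix(0, S, nn)
  for (g in seq_len(nrow(grid))) {
    asg <- as.integer(grid[g, ])
    state_of <- function(v) if (v <= nt) tipidx[v] else
      asg[v - nt]
    term <- prior
    for (v in internal) {
      oo <- ot[[asg[v - nt]]]
      c1 <- ch[v, 1]; c2 <- ch[v, 2]
      s1 <- state_of(c1); s2 <- state_of(c2)
      fac <- sum(oo$w * P[[c1]][oo$l, s1] * P[[c2]][oo$r, s2])
      term <- term * fac
    }
    L_tot <- L_tot + term
    for (v in internal) marg[asg[v - nt], v] <- marg[asg[v - nt], v] + term
  }
  list(loglik = log(L_tot), marginals = sweep(marg, 2, colSums(marg), "/"))
}

# random chronogram shapes with <= 4 tips used by the enumeration checks
small_tree_shapes <- function() {
  lapply(c("(t1:1.3,t2:1.3):0;",
           "((t1:1,t2:1):1.2,t3:2.2):0;",
           "((t1:1,t2:1):2,(t3:1.5,t4:1.5):1.5):0;",
           "(((t1:0.8,t2:0.8):0.7,t3:1.5):1,t4:2.5):0;"),
         parse_newick, mode = "chronogram")
}

random_tip_ranges <- function(tree, space) {
  labs <- space$labels[space$bits != 0L]
  tibble::tibble(species = tree$tip.label,
                 range = sample(labs, ape::Ntip(tree), replace = TRUE))
}

expect_rel_equal <- function(a, b, tol) {
  expect_lt(abs(a - b) / max(1e-12, abs(b)), tol)
}
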