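# DEC pruning likelihood, ML rate estimation, and marginal ancestral ranges.
#
# The likelihood follows the dispersal-extinction-cladogenesis model: ranges
# evolve anagenetically along branches by single-area gains (rate d per
# occupied area) and losses (rate e), and are partitioned between daughters
# at nodes by vicariance, peripheral isolation or (single-area) duplication.
# Tip partials are indicator vectors; branch propagation uses exp(Q t); node
# combination sums over cladogenetic outcomes; the root sums over non-null
# states under a uniform prior (the Lagrange default).

# Precompute everything that does not depend on (d, e).
dec_prepare <- function(tree, tip_ranges, space) {
  assert_chronogram(tree)
  ch <- children_of(tree, strict = TRUE) # errors on polytomies
  nt <- ape::Ntip(tree)
  labs <- normalize_names(tree$tip.label)
  sp_names <- normalize_names(tip_ranges$species)
  idx <- match(labs, sp_names)
  if (anyNA(idx)) {
    stop("tips missing from the range table: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  }
  bits <- range_bits(tip_ranges$range[idx], space$areas)
  if (any(bits == 0L)) stop("tip ranges must be non-null")
  st <- state_index(space, bits)
  if (anyNA(st)) {
    stop("tip range(s) not representable in the state space: ",
         paste(unique(tip_ranges$range[idx][is.na(st)]), collapse = ", "),
         " (pass them as `observed` to dec_state_space())")
  }
  list(tree = tree, space = space, children = ch,
       po_nodes = postorder_nodes(tree),
       plen = parent_edge_length(tree),
       tip_state = st, ntip = nt, root = nt + 1L,
       clado = clado_table(space))
}

normalize_names <- function(x) gsub("[ _]+", "_", trimws(x))

# Core pruning pass; optionally the outside pass for marginals.
dec_core <- function(prep, d, e, marginals = FALSE) {
  space <- prep$space
  S <- length(space$bits)
  Q <- dec_q_matrix(space, d, e)
  prop <- make_propagator(Q)
  cl <- prep$clado
  nt <- prep$ntip
  nn <- nt + prep$tree$Nnode
  D <- matrix(0, S, nn)       # node partials (pre-split, clado-summed)
  Dtop <- matrix(0, S, nn)    # branch-top partials, indexed by child node
  Pmats <- vector("list", nn) # per-branch transition matrices
  logscale <- 0
  prior <- c(0, rep(1 / (S - 1), S - 1))
  for (v in prep$po_nodes) {
    if (v <= nt) {
      D[prep$tip_state[v], v] <- 1
    } else {
      c1 <- prep$children[v, 1]; c2 <- prep$children[v, 2]
      P1 <- prop(prep$plen[c1]); P2 <- prop(prep$plen[c2])
      Pmats[[c1]] <- P1; Pmats[[c2]] <- P2
      t1 <- as.vector(P1 %*% D[, c1])
      t2 <- as.vector(P2 %*% D[, c2])
      Dtop[, c1] <- t1; Dtop[, c2] <- t2
      v_ <- cl$wts * t1[cl$lidx] * t2[cl$ridx]
      Dv <- as.vector(cl$Cp %*% v_)
      s <- sum(Dv)
      if (s <= 0) {
        return(list(loglik = -Inf, degenerate = TRUE))
      }
      D[, v] <- Dv / s
      logscale <- logscale + log(s)
    }
  }
  L <- sum(prior * D[, prep$root])
  out <- list(loglik = log(L) + logscale, degenerate = FALSE)
  if (!marginals) return(out)

  # outside pass: G[v] is the likelihood contribution from everything
  # outside v's subtree, as a function of v's pre-split range
  G <- matrix(0, S, nn)
  G[, prep$root] <- prior
  pre <- rev(prep$po_nodes)
  marg <- matrix(0, S, nn)
  for (v in pre) {
    if (v <= nt) next
    gm <- G[, v] * D[, v]
    gm[space$bits == 0L] <- 0
    marg[, v] <- gm / sum(gm)
    c1 <- prep$children[v, 1]; c2 <- prep$children[v, 2]
    v1 <- cl$wts * G[cl$pidx, v] * Dtop[cl$ridx, c2]
    F1 <- as.vector(cl$Cl %*% v1)
    g1 <- as.vector(crossprod(Pmats[[c1]], F1))
    s1 <- sum(g1); if (s1 > 0) g1 <- g1 / s1
    G[, c1] <- g1
    v2 <- cl$wts * G[cl$pidx, v] * Dtop[cl$lidx, c1]
    F2 <- as.vector(cl$Cr %*% v2)
    g2 <- as.vector(crossprod(Pmats[[c2]], F2))
    s2 <- sum(g2); if (s2 > 0) g2 <- g2 / s2
    G[, c2] <- g2
  }
  out$marginals <- marg
  out
}

#' DEC log-likelihood
#'
#' Pruning (post-order) likelihood of observed tip ranges on a dated binary
#' tree under the DEC model with rates `d` (dispersal) and `e` (local
#' extinction).
#'
#' @param tree An ultrametric binary `phylo` (ages in Myr).
#' @param tip_ranges Tibble with columns `species`, `range` (labels over the
#'   space's codebook), covering every tip.
#' @param d,e Nonnegative rates, per area per Myr.
#' @param space A `dec_space`; defaults to the 8-area, max-3 space enlarged
#'   by any oversized observed tip range.
#' @return The log-likelihood (scalar). Data impossible under the space give
#'   `-Inf` with a warning.
#' @examples
#' sp <- dec_state_space(c("A", "B"), 2)
#' tr <- parse_newick("(t1:1,t2:1):0;", "chronogram")
#' tips <- tibble::tibble(species = c("t1", "t2"), range = c("A", "A"))
#' dec_loglik(tr, tips, d = 0, e = 0, space = sp) # log(1/3)
#' @export
dec_loglik <- function(tree, tip_ranges, d, e,
                       space = dec_state_space(observed = tip_ranges$range)) {
  prep <- dec_prepare(tree, tip_ranges, space)
  res <- dec_core(prep, d, e)
  if (res$degenerate) {
    warning("all-zero partial likelihood: data impossible under this space")
  }
  res$loglik
}

#' Maximum-likelihood DEC rates
#'
#' Maximizes the DEC likelihood over `(d, e)` by bounded quasi-Newton on the
#' log scale.
#'
#' @inheritParams dec_loglik
#' @param start Starting values `c(d, e)` (default `c(0.01, 0.01)`).
#' @param lower,upper Box bounds on the rates.
#' @param multistart Number of additional random restarts (log-uniform
#'   within the bounds) for robustness; the best optimum is kept.
#' @return An object of class `dec_fit`: list with `d`, `e`, `loglik`,
#'   `convergence` (0 = converged), `counts`, and the inputs needed by
#'   [ancestral_range_marginals()].
#' @export
fit_dec_ml <- function(tree, tip_ranges, space =
                         dec_state_space(observed = tip_ranges$range),
                       start = c(0.01, 0.01), lower = 1e-7, upper = 100,
                       multistart = 0) {
  prep <- dec_prepare(tree, tip_ranges, space)
  nll <- function(lp) {
    r <- dec_core(prep, exp(lp[1]), exp(lp[2]))
    if (!is.finite(r$loglik)) return(1e10)
    -r$loglik
  }
  starts <- list(log(start))
  if (multistart > 0) {
    for (i in seq_len(multistart)) {
      starts <- c(starts, list(stats::runif(2, log(lower * 10),
                                            log(upper / 10))))
    }
  }
  best <- NULL
  for (s0 in starts) {
    o <- stats::optim(s0, nll, method = "L-BFGS-B",
                      lower = log(lower), upper = log(upper),
                      control = list(factr = 1e7, maxit = 500))
    if (is.null(best) || o$value < best$value) best <- o
  }
  structure(list(d = exp(best$par[1]), e = exp(best$par[2]),
                 loglik = -best$value, convergence = best$convergence,
                 counts = best$counts, n_tips = prep$ntip,
                 n_states = length(space$bits),
                 tree = tree, tip_ranges = tip_ranges, space = space),
            class = "dec_fit")
}

#' @exportS3Method base::print
print.dec_fit <- function(x, ...) {
  cat("DEC maximum-likelihood fit\n")
  cat(sprintf("  d = %.6g, e = %.6g  (per area per Myr)\n", x$d, x$e))
  cat(sprintf("  log-likelihood = %.4f over %d tips, %d range states\n",
              x$loglik, x$n_tips, x$n_states))
  if (x$convergence != 0) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' Marginal ancestral-range probabilities
#'
#' For every internal node, the posterior probability of each non-null range
#' at the node immediately before its cladogenetic split (the node's subtree
#' likelihood already sums over cladogenetic outcomes). Probabilities are
#' relative likelihoods normalized per node.
#'
#' @inheritParams dec_loglik
#' @param fit Alternatively, a `dec_fit`; its data and ML rates are used.
#' @return A tibble (class `rd_ranges`) with columns `node`, `age`, `range`,
#'   `prob` (rows with prob < `prune_tol` dropped); attribute `convention`
#'   records the reporting convention.
#' @param prune_tol Probabilities below this are omitted from the table
#'   (default 1e-10).
#' @export
ancestral_range_marginals <- function(tree, tip_ranges, d, e,
                                      space = dec_state_space(
                                        observed = tip_ranges$range),
                                      fit = NULL, prune_tol = 1e-10) {
  if (!is.null(fit)) {
    tree <- fit$tree; tip_ranges <- fit$tip_ranges
    d <- fit$d; e <- fit$e; space <- fit$space
  }
  prep <- dec_prepare(tree, tip_ranges, space)
  res <- dec_core(prep, d, e, marginals = TRUE)
  if (res$degenerate) stop("data impossible under this space")
  ages <- node_ages(tree)
  nt <- prep$ntip
  internal <- (nt + 1):(nt + tree$Nnode)
  rows <- lapply(internal, function(v) {
    p <- res$marginals[, v]
    keep <- p > prune_tol
    tibble::tibble(node = v, age = ages[v],
                   range = space$labels[keep], prob = p[keep])
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "convention") <- "pre-split range, cladogenesis-conditioned"
  attr(out, "params") <- c(d = d, e = e)
  class(out) <- c("rd_ranges", class(out))
  out
}
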