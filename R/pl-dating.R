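# Penalized-likelihood rate smoothing: Poisson likelihood of per-branch
# substitution counts, minus a smoothness penalty (weight S) on rate
# differences between adjacent branches, maximized jointly over node ages
# (crown age fixed by the calibration) and branch rates. Cross-validation
# over S leaves out one terminal branch at a time.

#' Penalized-likelihood dating configuration
#'
#' @param smoothing Penalty weight `S >= 0` (default 10).
#' @param calibration_age Fixed crown (root) age in Ma (default 70.1).
#' @param sites Alignment length used to convert branch lengths (expected
#'   substitutions/site) into expected substitution counts (default 4000).
#' @return A list of class `pl_config`.
#' @export
pl_config <- function(smoothing = 10, calibration_age = 70.1, sites = 4000) {
  stopifnot(smoothing >= 0, calibration_age > 0, sites > 0)
  structure(list(smoothing = smoothing, calibration_age = calibration_age,
                 sites = sites), class = "pl_config")
}

# shared precomputation
pl_prepare <- function(tree, config) {
  if (!is_binary_tree(tree)) stop("a fully resolved (binary) tree is required")
  nt <- ape::Ntip(tree)
  edge <- tree$edge
  n_k <- tree$edge.length * config$sites # real-valued expected counts
  pedge <- match(edge[, 1], edge[, 2])   # parent edge of each edge
  root_edges <- which(is.na(pedge))
  list(tree = tree, nt = nt, root = nt + 1L, edge = edge, n_k = n_k,
       pedge = pedge, root_edges = root_edges, nn = nt + tree$Nnode,
       po = postorder_nodes(tree), pre = rev(postorder_nodes(tree)),
       children = children_of(tree), config = config)
}

pl_core_value <- function(prep, ages, rates, weights = NULL) {
  t_k <- ages[prep$edge[, 1]] - ages[prep$edge[, 2]]
  if (any(t_k <= 0)) stop("zero or negative branch duration")
  n <- prep$n_k
  mu <- rates * t_k * prep$config$sites
  pois <- ifelse(n > 0, n * log(mu), 0) - mu
  if (!is.null(weights)) pois <- pois * weights
  hp <- !is.na(prep$pedge)
  # the penalty acts on whole-alignment rates (r * sites), the scale on
  # which the conventional smoothing values (S ~ 1-1000) are calibrated
  rs <- rates * prep$config$sites
  pen <- sum((rs[hp] - rs[prep$pedge[hp]])^2) +
    stats::var(rs[prep$root_edges])
  sum(pois) - prep$config$smoothing * pen
}

#' Penalized-likelihood objective
#'
#' The dating objective: `sum_k [n_k log(mu_k) - mu_k]` over branches, with
#' `n_k` = branch length x sites (real-valued expected substitution count)
#' and Poisson mean `mu_k = r_k * sites * t_k`, minus
#' `S * [sum (R_k - R_parent(k))^2 + var(root children's R)]` where
#' `R_k = r_k * sites` is the whole-alignment rate (the scale on which
#' conventional smoothing values are calibrated). The constant `log(n_k!)`
#' term is omitted (it affects no optimization).
#'
#' @param tree A phylogram (`phylo`, branch lengths in expected
#'   substitutions/site).
#' @param ages Numeric vector of node ages (Ma) indexed by ape node number
#'   (tips first); must satisfy parent > child.
#' @param rates Numeric vector of per-branch rates
#'   (substitutions/site/Myr, > 0) in `tree$edge` order.
#' @param config A [pl_config()].
#' @return The penalized log-likelihood (scalar).
#' @export
pl_objective <- function(tree, ages, rates, config = pl_config()) {
  prep <- pl_prepare(tree, config)
  stopifnot(length(rates) == nrow(tree$edge), all(rates > 0))
  pl_core_value(prep, ages, rates)
}

# objective + gradient in the transformed parameterization:
# par = c(logit(u) for internal non-root nodes, log(rates))
pl_transformed <- function(prep, weights = NULL) {
  nt <- prep$nt; root <- prep$root; nn <- prep$nn
  free_nodes <- setdiff((nt + 1):nn, root)
  ne <- nrow(prep$edge)
  parent_node <- parent_of(prep$tree)
  calib <- prep$config$calibration_age
  S <- prep$config$smoothing
  n <- prep$n_k
  w <- if (is.null(weights)) rep(1, ne) else weights
  hp <- !is.na(prep$pedge)
  re <- prep$root_edges
  m <- length(re)
  edge1 <- prep$edge[, 1]; edge2 <- prep$edge[, 2]
  # edges grouped by parent edge for the penalty gradient
  kids_of_edge <- split(seq_len(ne)[hp], prep$pedge[hp])

  ages_of <- function(u) {
    a <- numeric(nn)
    a[root] <- calib
    for (v in prep$pre) {
      if (v == root || v <= nt) next
      a[v] <- u[v] * a[parent_node[v]]
    }
    a
  }
  list(
    free_nodes = free_nodes, ne = ne, ages_of = ages_of,
    fn = function(par) {
      u <- numeric(nn)
      u[free_nodes] <- stats::plogis(par[seq_along(free_nodes)])
      r <- exp(par[length(free_nodes) + seq_len(ne)])
      a <- ages_of(u)
      t_k <- a[edge1] - a[edge2]
      mu <- r * t_k * prep$config$sites
      pois <- (ifelse(n > 0, n * log(mu), 0) - mu) * w
      rs <- r * prep$config$sites
      pen <- sum((rs[hp] - rs[prep$pedge[hp]])^2) + stats::var(rs[re])
      -(sum(pois) - S * pen)
    },
    gr = function(par) {
      u <- numeric(nn)
      u[free_nodes] <- stats::plogis(par[seq_along(free_nodes)])
      r <- exp(par[length(free_nodes) + seq_len(ne)])
      a <- ages_of(u)
      t_k <- a[edge1] - a[edge2]
      sites <- prep$config$sites
      dLdt <- (ifelse(n > 0, n / t_k, 0) - r * sites) * w
      # rate gradient (on log scale); penalty acts on r * sites
      rs <- r * sites
      dpen <- numeric(ne)
      dpen[hp] <- 2 * (rs[hp] - rs[prep$pedge[hp]])
      for (k in names(kids_of_edge)) {
        kk <- as.integer(k)
        dpen[kk] <- dpen[kk] - 2 * sum(rs[kids_of_edge[[k]]] - rs[kk])
      }
      dpen[re] <- dpen[re] + 2 * (rs[re] - mean(rs[re])) / (m - 1)
      g_lr <- (ifelse(n > 0, n, 0) - r * t_k * sites) * w -
        S * rs * dpen
      # age gradient, chained through the u parameterization
      g_a <- numeric(nn)
      for (k in seq_len(ne)) {
        g_a[edge1[k]] <- g_a[edge1[k]] + dLdt[k]
        g_a[edge2[k]] <- g_a[edge2[k]] - dLdt[k]
      }
      s_acc <- numeric(nn)
      for (v in prep$po) {
        if (v <= nt) next
        s_acc[v] <- g_a[v] * a[v]
        for (c_ in prep$children[v, ]) {
          if (c_ > nt) s_acc[v] <- s_acc[v] + s_acc[c_]
        }
      }
      g_eta <- s_acc[free_nodes] * (1 - u[free_nodes])
      -c(g_eta, g_lr)
    })
}

#' Fit a penalized-likelihood chronogram
#'
#' Converts a phylogram into a chronogram under a fixed crown age,
#' maximizing [pl_objective()] jointly over node ages (parameterized as
#' per-node fractions of the parent age, so the age order constraint holds
#' by construction) and log branch rates, with analytic gradients and
#' box-constrained quasi-Newton.
#'
#' @param tree A binary rooted phylogram.
#' @param config A [pl_config()].
#' @param prune Optional tip labels (e.g. an outgroup) dropped before
#'   fitting.
#' @param multistart Additional jittered restarts.
#' @return A `pl_fit`: list with `chronogram` (ultrametric `phylo`, branch
#'   lengths in Myr), `ages` (per node), `rates` (tibble per edge),
#'   `objective`, `convergence`, `config`.
#' @export
fit_pl <- function(tree, config = pl_config(), prune = NULL,
                   multistart = 0) {
  if (!is.null(prune) && length(prune) > 0) {
    tree <- ape::drop.tip(tree, prune)
  }
  prep <- pl_prepare(tree, config)
  tf <- pl_transformed(prep)
  par0 <- pl_start(prep, tf)
  lower <- c(rep(-12, length(tf$free_nodes)), rep(-25, tf$ne))
  upper <- c(rep(12, length(tf$free_nodes)), rep(8, tf$ne))
  run <- function(p0) {
    stats::optim(p0, tf$fn, tf$gr, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(maxit = 5000, factr = 1e7))
  }
  best <- run(par0)
  if (multistart > 0) {
    for (i in seq_len(multistart)) {
      o <- run(par0 + stats::rnorm(length(par0), 0, 0.3))
      if (o$value < best$value) best <- o
    }
  }
  u <- numeric(prep$nn)
  u[tf$free_nodes] <- stats::plogis(best$par[seq_along(tf$free_nodes)])
  rates <- exp(best$par[length(tf$free_nodes) + seq_len(tf$ne)])
  ages <- tf$ages_of(u)
  chrono <- tree
  chrono$edge.length <- ages[prep$edge[, 1]] - ages[prep$edge[, 2]]
  structure(list(
    chronogram = chrono, ages = ages,
    rates = tibble::tibble(edge = seq_len(tf$ne),
                           parent = prep$edge[, 1], child = prep$edge[, 2],
                           rate = rates),
    objective = -best$value, convergence = best$convergence,
    counts = best$counts, config = config), class = "pl_fit")
}

# heuristic start: ages proportional to maximal root-to-tip substitution
# path depths; one global clock rate (penalty starts at zero)
pl_start <- function(prep, tf) {
  nt <- prep$nt
  md <- numeric(prep$nn) # max substitution path from node down to a tip
  bl <- parent_edge_length(prep$tree)
  for (v in prep$po) {
    if (v <= nt) next
    for (c_ in prep$children[v, ]) {
      md[v] <- max(md[v], md[c_] + bl[c_])
    }
  }
  a0 <- numeric(prep$nn)
  a0[prep$root] <- prep$config$calibration_age
  parent_node <- parent_of(prep$tree)
  u0 <- numeric(prep$nn)
  for (v in prep$pre) {
    if (v == prep$root || v <= nt) next
    frac <- if (md[parent_node[v]] > 0) md[v] / md[parent_node[v]] else 0.5
    u0[v] <- min(max(frac, 0.02), 0.98)
    a0[v] <- u0[v] * a0[parent_node[v]]
  }
  t0 <- a0[prep$edge[, 1]] - a0[prep$edge[, 2]]
  r0 <- max(sum(prep$n_k) / (prep$config$sites * sum(t0)), 1e-8)
  c(stats::qlogis(u0[tf$free_nodes]), rep(log(r0), tf$ne))
}

#' @exportS3Method base::print
print.pl_fit <- function(x, ...) {
  cat("Penalized-likelihood chronogram\n")
  cat(sprintf("  crown age %.4g Ma (fixed), S = %g, objective = %.4f\n",
              x$config$calibration_age, x$config$smoothing, x$objective))
  cat(sprintf("  rate range [%.3g, %.3g] subst/site/Myr\n",
              min(x$rates$rate), max(x$rates$rate)))
  if (x$convergence != 0) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' Cross-validation over the smoothing parameter
#'
#' For each `S` in a grid, refits the dating once per terminal branch with
#' that branch's substitution count removed from the likelihood (the
#' branch's rate stays in the penalty, so it is smoothed from its
#' neighbours), predicts the held-out count as the parent-adjacent fitted
#' rate times the fitted duration, and scores
#' `sum (n_k - pred_k)^2 / pred_k`. Lower is better.
#'
#' @inheritParams fit_pl
#' @param S_grid Numeric vector of smoothing values.
#' @return A tibble (`S`, `cv_score`, `n_folds_failed`) with attribute
#'   `best_S` (argmin).
#' @export
cross_validate_smoothing <- function(tree, config = pl_config(),
                                     S_grid = c(0.1, 1, 10, 100)) {
  nt <- ape::Ntip(tree)
  term <- which(tree$edge[, 2] <= nt)
  if (length(term) < 5) stop("need at least 5 terminal branches")
  rows <- lapply(S_grid, function(S) {
    cfg <- pl_config(S, config$calibration_age, config$sites)
    prep <- pl_prepare(tree, cfg)
    full <- fit_pl(tree, cfg)
    tf_full <- pl_transformed(prep)
    warm <- c(stats::qlogis(pmin(pmax(
      full$ages[tf_full$free_nodes] /
        full$ages[parent_of(tree)[tf_full$free_nodes]], 1e-6), 1 - 1e-6)),
      log(full$rates$rate))
    score <- 0; failed <- 0L
    for (k in term) {
      w <- rep(1, nrow(tree$edge)); w[k] <- 0
      tf <- pl_transformed(prep, weights = w)
      o <- tryCatch(
        stats::optim(warm, tf$fn, tf$gr, method = "L-BFGS-B",
                     lower = c(rep(-12, length(tf$free_nodes)),
                               rep(-25, tf$ne)),
                     upper = c(rep(12, length(tf$free_nodes)),
                               rep(8, tf$ne)),
                     control = list(maxit = 3000, factr = 1e7)),
        error = function(e) NULL)
      if (is.null(o)) { failed <- failed + 1L; next }
      u <- numeric(prep$nn)
      u[tf$free_nodes] <- stats::plogis(o$par[seq_along(tf$free_nodes)])
      r <- exp(o$par[length(tf$free_nodes) + seq_len(tf$ne)])
      a <- tf$ages_of(u)
      t_k <- a[tree$edge[k, 1]] - a[tree$edge[k, 2]]
      pk <- prep$pedge[k]
      r_adj <- if (!is.na(pk)) r[pk] else
        mean(r[setdiff(prep$root_edges, k)])
      pred <- max(r_adj * t_k * cfg$sites, 1e-12)
      score <- score + (prep$n_k[k] - pred)^2 / pred
    }
    tibble::tibble(S = S, cv_score = score, n_folds_failed = failed)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "best_S") <- out$S[which.min(out$cv_score)]
  out
}

#' Date a sample of phylograms and summarize clade ages
#'
#' Applies [fit_pl()] with one shared smoothing value to every tree of a
#' sample (e.g. trees drawn from a Bayesian posterior), then summarizes
#' per-clade age means and 95% intervals on a reference tree via
#' [clade_ages_across_trees()]. Individual failures are logged; more than
#' `max_fail_frac` failures abort.
#'
#' @param trees A list of binary rooted phylograms with identical tip sets.
#' @param config A [pl_config()].
#' @param reference Optional reference chronogram; default: the first
#'   successfully dated tree.
#' @param max_fail_frac Abort threshold (default 0.1).
#' @return A list: `chronograms`, `summary` (clade age tibble), `failures`
#'   (integer indices), `config`.
#' @export
date_tree_sample <- function(trees, config = pl_config(), reference = NULL,
                             max_fail_frac = 0.1) {
  fits <- vector("list", length(trees))
  failures <- integer(0)
  for (i in seq_along(trees)) {
    fits[[i]] <- tryCatch(fit_pl(trees[[i]], config),
                          error = function(e) e)
    if (inherits(fits[[i]], "error")) failures <- c(failures, i)
  }
  if (length(failures) > max_fail_frac * length(trees)) {
    stop("penalized-likelihood dating failed on ", length(failures), " of ",
         length(trees), " trees: ",
         conditionMessage(fits[[failures[1]]]))
  }
  chronos <- lapply(fits[setdiff(seq_along(fits), failures)],
                    function(f) f$chronogram)
  if (is.null(reference)) reference <- chronos[[1]]
  list(chronograms = chronos,
       summary = clade_ages_across_trees(reference, chronos),
       failures = failures, config = config)
}
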