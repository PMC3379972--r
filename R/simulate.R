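# Ground-truth simulators: state-dependent birth-death trees (plain
# birth-death and GeoSSE), DEC range histories with recorded events, and
# autocorrelated substitution-rate variation turning chronograms into
# phylograms.
#
# All simulators are deterministic under a fixed seed; per-module seeds are
# derived as fixed offsets of one master seed so adding a simulator does not
# perturb existing draws.

#' Derive a per-module substream seed
#'
#' @param seed Master integer seed.
#' @param module One of `"trees"`, `"dec"`, `"geosse"`, `"rates"`,
#'   `"pipeline"`.
#' @return An integer seed below 2^31.
#' @export
substream_seed <- function(seed, module) {
  off <- c(trees = 101L, dec = 211L, geosse = 307L, rates = 401L,
           pipeline = 503L)
  if (!module %in% names(off)) stop("unknown module: ", module)
  as.integer((as.double(seed) + off[[module]] * 1009) %% 2147483647)
}

# Generic Gillespie simulator for lineage trees with K states.
# birth[k]: speciation rate in state k; birth_kids: function(k) -> c(s1,s2)
# daughter states; death[k]; trans: K x K anagenetic rate matrix (diag 0).
# Stops at n_tips extant lineages or at crown_age. Conditions on both crown
# lineages leaving extant descendants (rejection, capped).
sim_sse_tree <- function(birth, birth_kids, death, trans,
                         root_children_states, n_tips = NULL,
                         crown_age = NULL, seed = NULL,
                         max_reject = 1000) {
  if (is.null(n_tips) == is.null(crown_age)) {
    stop("give exactly one of n_tips or crown_age")
  }
  if (!is.null(seed)) set.seed(seed)
  K <- length(birth)
  trans_tot <- rowSums(trans)
  rate_of <- function(s) birth[s] + death[s] + trans_tot[s]
  for (attempt in seq_len(max_reject)) {
    st0 <- root_children_states()
    parent <- c(0L, 0L); t_start <- c(0, 0); state <- st0
    t_end <- c(NA_real_, NA_real_); endt <- c(NA_integer_, NA_integer_)
    kid1 <- c(NA_integer_, NA_integer_); kid2 <- kid1
    half <- c(1L, 2L)
    active <- c(1L, 2L)
    t <- 0
    repeat {
      rates <- rate_of(state[active])
      tot <- sum(rates)
      if (tot <= 0) { # nothing can happen; everything survives
        if (!is.null(crown_age)) { t <- crown_age; break }
        t <- Inf; break
      }
      dt <- stats::rexp(1, tot)
      if (!is.null(crown_age) && t + dt >= crown_age) { t <- crown_age; break }
      t <- t + dt
      i <- active[sample.int(length(active), 1, prob = rates)]
      s <- state[i]
      u <- stats::runif(1) * rate_of(s)
      if (u < birth[s]) { # speciation
        ks <- birth_kids(s)
        n0 <- length(parent)
        parent <- c(parent, i, i); t_start <- c(t_start, t, t)
        state <- c(state, ks); t_end <- c(t_end, NA, NA)
        endt <- c(endt, NA, NA); kid1 <- c(kid1, NA, NA); kid2 <- c(kid2, NA, NA)
        half <- c(half, half[i], half[i])
        t_end[i] <- t; endt[i] <- 2L; kid1[i] <- n0 + 1L; kid2[i] <- n0 + 2L
        active <- c(active[active != i], n0 + 1L, n0 + 2L)
        if (!is.null(n_tips) && length(active) == n_tips) break
      } else if (u < birth[s] + death[s]) { # extinction
        t_end[i] <- t; endt[i] <- 1L
        active <- active[active != i]
        if (length(active) == 0) break
      } else { # anagenetic transition
        pr <- trans[s, ]
        state[i] <- sample.int(K, 1, prob = pr)
      }
    }
    if (length(active) < 2) next
    if (!all(c(1L, 2L) %in% unique(half[active]))) next
    if (!is.null(n_tips)) {
      # extend the present by a fresh waiting time so the youngest node has
      # positive age (stopping exactly at the n-th birth leaves it at 0)
      tot <- sum(rate_of(state[active]))
      if (tot > 0) t <- t + stats::rexp(1, tot)
    }
    t_end[active] <- t; endt[active] <- 0L
    # build newick over all lineages, then drop extinct tips
    fmt <- function(z) sprintf("%.10g", z)
    lab <- paste0("t", seq_along(parent))
    nwk <- function(i) {
      len <- fmt(t_end[i] - t_start[i])
      if (endt[i] == 2L) {
        paste0("(", nwk(kid1[i]), ",", nwk(kid2[i]), "):", len)
      } else paste0(lab[i], ":", len)
    }
    txt <- paste0("(", nwk(1L), ",", nwk(2L), "):0;")
    phy <- ape::read.tree(text = txt)
    extinct <- lab[which(endt == 1L)]
    if (length(extinct) > 0) phy <- ape::drop.tip(phy, extinct)
    if (is.null(phy) || ape::Ntip(phy) < 2) next
    states <- stats::setNames(state[endt == 0L], lab[endt == 0L])
    states <- states[phy$tip.label]
    return(list(phy = phy, states = states, age = t,
                rejected = attempt - 1L))
  }
  stop("simulation rejected ", max_reject,
       " times (total extinction or crown failure)")
}

#' Simulate a birth-death chronogram
#'
#' Forward (Gillespie) constant-rate birth-death simulation from two crown
#' lineages, conditioned on both crown lineages leaving extant descendants;
#' extinct lineages are pruned. Stop either at a fixed number of extant
#' tips or at a fixed crown age.
#'
#' @param birth,death Speciation and extinction rates (/Myr); `birth > 0`,
#'   `death >= 0`.
#' @param n_tips,crown_age Exactly one must be given.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param max_reject Rejection cap before erroring.
#' @return An ultrametric `phylo`.
#' @export
simulate_bd_tree <- function(birth, death = 0, n_tips = NULL,
                             crown_age = NULL, seed, max_reject = 1000) {
  stopifnot(birth > 0, death >= 0)
  sim <- sim_sse_tree(birth = birth, birth_kids = function(s) c(1L, 1L),
                      death = death, trans = matrix(0, 1, 1),
                      root_children_states = function() c(1L, 1L),
                      n_tips = n_tips, crown_age = crown_age, seed = seed,
                      max_reject = max_reject)
  sim$phy
}

#' Simulate a GeoSSE tree and tip states
#'
#' Forward simulation of the three-state (A, B, AB) geographic
#' speciation-extinction process: within-region speciation `sA`, `sB`
#' (an AB parent leaves daughters (A, AB) or (B, AB)), between-region
#' speciation `sAB` (daughters (A, B)), extinction `xA`, `xB` (an AB
#' lineage contracts instead of dying), and range expansion `dA` (A to AB)
#' and `dB` (B to AB). Extinct lineages are pruned.
#'
#' @param pars Named vector `sA, sB, sAB, xA, xB, dA, dB` (all >= 0, at
#'   least one speciation rate > 0).
#' @inheritParams simulate_bd_tree
#' @param root_state `"A"`, `"B"` or `"AB"` (default): crown daughter
#'   states are drawn from the root state's cladogenetic outcomes.
#' @return A list: `tree` (ultrametric `phylo`), `states` (tibble
#'   `species`/`state` with states `A`, `B`, `AB`).
#' @export
simulate_geosse <- function(pars, n_tips = NULL, crown_age = NULL, seed,
                            root_state = "AB", max_reject = 1000) {
  p <- geosse_pars(pars)
  if (p[["sA"]] + p[["sB"]] + p[["sAB"]] <= 0) {
    stop("at least one speciation rate must be positive")
  }
  birth <- c(p[["sA"]], p[["sB"]], p[["sA"]] + p[["sB"]] + p[["sAB"]])
  death <- c(p[["xA"]], p[["xB"]], 0)
  trans <- matrix(0, 3, 3)
  trans[1, 3] <- p[["dA"]]; trans[2, 3] <- p[["dB"]]
  trans[3, 1] <- p[["xB"]]; trans[3, 2] <- p[["xA"]]
  kids <- function(s) {
    if (s == 1L) return(c(1L, 1L))
    if (s == 2L) return(c(2L, 2L))
    w <- c(p[["sA"]], p[["sB"]], p[["sAB"]])
    k <- sample.int(3, 1, prob = w)
    if (k == 1L) c(1L, 3L) else if (k == 2L) c(2L, 3L) else c(1L, 2L)
  }
  rs <- match(root_state, c("A", "B", "AB"))
  if (is.na(rs)) stop("root_state must be A, B or AB")
  root_fun <- function() kids(rs)
  sim <- sim_sse_tree(birth, kids, death, trans, root_fun,
                      n_tips = n_tips, crown_age = crown_age, seed = seed,
                      max_reject = max_reject)
  lv <- c("A", "B", "AB")
  list(tree = sim$phy,
       states = tibble::tibble(species = names(sim$states),
                               state = lv[sim$states]))
}

#' Simulate a DEC range history on a fixed chronogram
#'
#' Draws a root range, a cladogenetic outcome at every node (with the
#' uniform DEC inheritance weights), and exact event-time (Gillespie)
#' anagenesis along every branch from the DEC rate matrix. Branch histories
#' absorbed in the null range are redrawn (conditioning on survival of the
#' observed lineages); every realized dispersal and extinction event is
#' recorded with its age.
#'
#' @param tree An ultrametric binary `phylo` (ages in Myr).
#' @param d,e DEC rates.
#' @param space A `dec_space`.
#' @param seed Integer seed.
#' @param root_range Optional root range label; default: uniform draw over
#'   non-null states.
#' @return A list: `tip_ranges` (tibble `species`/`range`), `node_ranges`
#'   (tibble `node`/`range`, the pre-split true states), `events` (tibble
#'   `kind`, `area`, `source`, `time`, `parent`, `child`, `from_root`),
#'   `n_redrawn` (branch redraws due to null absorption).
#' @export
simulate_dec_history <- function(tree, d, e, space = dec_state_space(),
                                 seed, root_range = NULL) {
  set.seed(seed)
  assert_chronogram(tree)
  ch <- children_of(tree, strict = TRUE)
  ages <- node_ages(tree)
  nt <- ape::Ntip(tree)
  root <- nt + 1L
  codes <- space$areas
  n <- length(codes)
  nonnull <- space$bits[space$bits != 0L]
  root_bits <- if (is.null(root_range)) {
    nonnull[sample.int(length(nonnull), 1)]
  } else range_bits(root_range, codes)
  redraws <- 0L
  events <- list()
  node_bits <- integer(nt + tree$Nnode)
  tip_bits <- integer(nt)

  draw_outcome <- function(b) {
    pr <- clado_pairs(b, n)
    keep <- !is.na(state_index(space, pr$left)) &
      !is.na(state_index(space, pr$right))
    pr <- pr[keep, , drop = FALSE]
    k <- sample.int(nrow(pr), 1)
    c(pr$left[k], pr$right[k])
  }
  sim_branch <- function(b0, age0, age1) {
    for (try_ in seq_len(10000)) {
      b <- b0; t <- age0; ev <- list()
      ok <- TRUE
      repeat {
        occ <- bits_areas_idx(b, n)
        gains <- integer(0)
        for (j in setdiff(seq_len(n), occ)) {
          if (!is.na(state_index(space, bitwOr(b, bitwShiftL(1L, j - 1L))))) {
            gains <- c(gains, j)
          }
        }
        r_gain <- rep(d * length(occ), length(gains))
        r_loss <- rep(e, length(occ))
        tot <- sum(r_gain) + sum(r_loss)
        if (tot <= 0) break
        dt <- stats::rexp(1, tot)
        if (t - dt <= age1) break
        t <- t - dt
        pick <- sample.int(length(gains) + length(occ), 1,
                           prob = c(r_gain, r_loss))
        if (pick <= length(gains)) {
          j <- gains[pick]
          ev[[length(ev) + 1]] <- list(kind = "dispersal", area = codes[j],
                                       source = range_label(b, codes),
                                       time = t)
          b <- bitwOr(b, bitwShiftL(1L, j - 1L))
        } else {
          j <- occ[pick - length(gains)]
          nb <- bitwAnd(b, bitwNot(bitwShiftL(1L, j - 1L)))
          if (nb == 0L) { ok <- FALSE; break } # null absorption: redraw
          ev[[length(ev) + 1]] <- list(kind = "extinction", area = codes[j],
                                       source = range_label(b, codes),
                                       time = t)
          b <- nb
        }
      }
      if (ok) return(list(bits = b, events = ev))
      redraws <<- redraws + 1L
    }
    stop("branch history rejected 10000 times (null absorption)")
  }

  recurse <- function(v, b_in) {
    if (v <= nt) { tip_bits[v] <<- b_in; return(invisible()) }
    node_bits[v] <<- b_in
    dt <- draw_outcome(b_in)
    for (k in 1:2) {
      cc <- ch[v, k]
      br <- sim_branch(dt[k], ages[v], ages[cc])
      for (evi in br$events) {
        events[[length(events) + 1]] <<- tibble::tibble(
          kind = evi$kind, area = evi$area, source = evi$source,
          time = evi$time, parent = v, child = cc, from_root = v == root)
      }
      recurse(cc, br$bits)
    }
  }
  recurse(root, root_bits)
  ev <- if (length(events) > 0) dplyr::bind_rows(events) else
    tibble::tibble(kind = character(0), area = character(0),
                   source = character(0), time = numeric(0),
                   parent = integer(0), child = integer(0),
                   from_root = logical(0))
  attr(ev, "root_age") <- ages[root]
  class(ev) <- c("rd_events", class(ev))
  list(
    tip_ranges = tibble::tibble(species = tree$tip.label,
                                range = range_label(tip_bits, codes)),
    node_ranges = tibble::tibble(node = (nt + 1):(nt + tree$Nnode),
                                 range = range_label(
                                   node_bits[(nt + 1):(nt + tree$Nnode)],
                                   codes)),
    events = ev, n_redrawn = redraws)
}

#' Simulate autocorrelated rate variation (chronogram to phylogram)
#'
#' Assigns each branch a substitution rate equal to its parent branch's
#' rate times a lognormal(0, `autocorr_sd`) factor (root branches start at
#' `base_rate` times the factor), then draws the observed branch length as
#' Poisson(rate x duration x sites)/sites.
#'
#' @param tree An ultrametric `phylo` (ages in Myr).
#' @param base_rate Clock rate in substitutions/site/Myr (> 0).
#' @param autocorr_sd Lognormal sd of the per-branch rate multiplier
#'   (0 = strict clock).
#' @param sites Alignment length in sites.
#' @param seed Integer seed.
#' @return A `phylo` phylogram; attribute `rates` holds the true per-edge
#'   rates (in `tree`'s edge order).
#' @export
simulate_rate_variation <- function(tree, base_rate, autocorr_sd = 0,
                                    sites = 4000, seed) {
  stopifnot(base_rate > 0, sites > 0, autocorr_sd >= 0)
  set.seed(seed)
  ne <- nrow(tree$edge)
  # parent edge index for each edge (NA for root children)
  pedge <- match(tree$edge[, 1], tree$edge[, 2])
  ord <- order(ape::node.depth.edgelength(tree)[tree$edge[, 2]]) # top-down
  rates <- numeric(ne)
  for (i in ord) {
    r0 <- if (is.na(pedge[i])) base_rate else rates[pedge[i]]
    rates[i] <- r0 * exp(stats::rnorm(1, 0, autocorr_sd))
  }
  phy <- tree
  lam <- rates * tree$edge.length * sites
  phy$edge.length <- stats::rpois(ne, lam) / sites
  attr(phy, "rates") <- rates
  phy
}

#' Paper-shaped simulation recipe
#'
#' Default study conditions for the end-to-end pipeline: a crown-age 70.1 Ma
#' birth-death tree expected to hold roughly 256 extant tips, the 8-area
#' codebook with DEC ranges rooted in the dominant source area (sub-Saharan
#' Africa, `C`), and a plastid-like phylogram (base rate 7e-4
#' substitutions/site/Myr, mild autocorrelated rate variation, 4000 sites).
#'
#' @param seed Master seed.
#' @return A list of class `rd_recipe` with components `seed`, `tree`,
#'   `dec`, `rates`, `geosse_settings`.
#' @export
default_recipe <- function(seed) {
  structure(list(
    seed = as.integer(seed),
    tree = list(birth = 0.10, death = 0.031, crown_age = 70.1,
                min_tips = 150, max_tips = 400),
    dec = list(d = 0.0025, e = 0.001, root_range = "C", max_range_size = 3),
    rates = list(base_rate = 7e-4, autocorr_sd = 0.25, sites = 4000),
    geosse_settings = list(generations = 20000, burnin = 5000)),
    class = "rd_recipe")
}

#' Run a simulation recipe
#'
#' Simulates the tree, the DEC range history and the phylogram of a recipe,
#' with per-module substream seeds.
#'
#' @param recipe An `rd_recipe` from [default_recipe()].
#' @return A list: `tree` (true chronogram), `history` (DEC history, see
#'   [simulate_dec_history()]), `tip_ranges`, `phylogram`, `space`,
#'   `recipe` (echo).
#' @export
simulate_recipe <- function(recipe) {
  stopifnot(inherits(recipe, "rd_recipe"))
  tr <- recipe$tree
  # condition the crown-age simulation on a study-sized tree
  phy <- NULL
  for (k in 0:200) {
    cand <- simulate_bd_tree(tr$birth, tr$death, crown_age = tr$crown_age,
                             seed = substream_seed(recipe$seed + k, "trees"))
    if (ape::Ntip(cand) >= tr$min_tips && ape::Ntip(cand) <= tr$max_tips) {
      phy <- cand; break
    }
  }
  if (is.null(phy)) stop("no tree within the recipe's tip-count window")
  space <- dec_state_space(max_range_size = recipe$dec$max_range_size)
  hist <- simulate_dec_history(phy, recipe$dec$d, recipe$dec$e, space,
                               seed = substream_seed(recipe$seed, "dec"),
                               root_range = recipe$dec$root_range)
  gram <- simulate_rate_variation(phy, recipe$rates$base_rate,
                                  recipe$rates$autocorr_sd,
                                  recipe$rates$sites,
                                  seed = substream_seed(recipe$seed, "rates"))
  list(tree = phy, history = hist, tip_ranges = hist$tip_ranges,
       phylogram = gram, space = space, recipe = recipe)
}
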